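#' Morphology template bank
#'
#' Noiseless side-view projections of the three reference morphologies —
#' cofilin-decorated actin, bare f-actin, and a featureless rod — rendered
#' at a grid of azimuthal phases so template matching is rotationally
#' pre-aligned.
#'
#' @param box Image size `(ny, nz)`, pixels.
#' @param apix Pixel size, Angstrom.
#' @param n_phases Number of azimuthal phases per morphology.
#' @return Named list (`cofilactin`, `factin`, `other`) of arrays
#'   `ny x nz x n_phases`.
#' @export
morphology_templates <- function(box = c(32L, 48L), apix = 11.81,
                                 n_phases = 18L) {
  box <- rep_len(as.integer(box), 2L)
  phases <- seq(0, 360, length.out = n_phases + 1L)[-(n_phases + 1L)]
  bank <- function(label) {
    a <- array(0, c(box, n_phases))
    for (i in seq_len(n_phases))
      a[, , i] <- .render_morphology_projection(label, phases[i], box, apix)
    a
  }
  list(cofilactin = bank("cofilactin"), factin = bank("factin"),
       other = bank("other"))
}

# Normalized cross-correlation between an image and every slice of a bank;
# returns the maximum.
.ncc_max <- function(img, bank) {
  v <- as.vector(img)
  v <- v - mean(v)
  nv <- sqrt(sum(v^2))
  best <- -1
  for (i in seq_len(dim(bank)[3])) {
    t_ <- as.vector(bank[, , i])
    t_ <- t_ - mean(t_)
    cc <- sum(v * t_) / (nv * sqrt(sum(t_^2)))
    if (is.finite(cc) && cc > best) best <- cc
  }
  best
}

#' Classify particles by template correlation
#'
#' Surrogate for reference-based 3D classification: each particle image is
#' labelled by the morphology whose (rotationally pre-aligned) template
#' bank achieves the highest normalized cross-correlation.
#'
#' @param images Array `ny x nz x n` of particle images.
#' @param templates Template bank from [morphology_templates()]; must
#'   match the particle grid.
#' @return Data.frame with `label` and `score` (winning correlation) per
#'   particle.
#' @export
classify_by_template <- function(images, templates) {
  d <- dim(images)
  td <- dim(templates[[1L]])
  if (!identical(d[1:2], td[1:2]))
    stop("particle and template grids differ")
  n <- if (length(d) == 3L) d[3] else 1L
  labels <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    img <- if (length(d) == 3L) images[, , i] else images
    cc <- vapply(templates, function(b) .ncc_max(img, b), 0)
    labels[i] <- names(templates)[which.max(cc)]
    scores[i] <- max(cc)
  }
  data.frame(label = labels, score = scores, stringsAsFactors = FALSE)
}

# Translation-invariant particle feature: unit-norm amplitude spectrum of
# the mean-subtracted image. Particles of one morphology share layer-line
# content (cross-over frequency, decoration width) but differ in azimuthal
# phase and axial register; clustering on the amplitude spectrum groups
# them by morphology the way helically constrained classification does,
# without modelling the alignment itself.
.image_feature <- function(img) {
  f <- Mod(stats::fft(img - mean(img)))
  v <- as.vector(f)
  v / sqrt(sum(v^2))
}

.bank_feature <- function(bank) {
  f <- 0
  for (i in seq_len(dim(bank)[3])) f <- f + .image_feature(bank[, , i])
  f / sqrt(sum(f^2))
}

#' Run one surrogate 3D-classification pass
#'
#' Emulates a single multi-class classification run: particles are
#' clustered into `n_classes` by k-means on translation-invariant
#' amplitude-spectrum features (initialized from randomly drawn particles;
#' the run's reference twist and class count select the initialization
#' stream, which is where run-to-run variability enters), each class
#' average is labelled by correlation against the template features, and
#' every particle inherits its class's morphology.
#'
#' @param images Array `ny x nz x n`.
#' @param n_classes Number of classes (the protocol uses 5, 10 or 20).
#' @param templates Template bank from [morphology_templates()].
#' @param seed Integer seed for the initialization.
#' @return List with `class_of` (class id per particle), `class_map`
#'   (morphology per class) and `labels` (morphology per particle).
#' @export
run_morphology_classification <- function(images, n_classes, templates,
                                          seed = 1L) {
  d <- dim(images)
  n <- d[3]
  if (n < n_classes) stop("fewer particles than classes")
  X <- t(vapply(seq_len(n), function(i) .image_feature(images[, , i]),
                numeric(d[1] * d[2])))
  set.seed(seed)
  init <- X[sample(n, n_classes), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(X, centers = init, iter.max = 20L))
  tfeat <- lapply(templates, .bank_feature)
  class_map <- character(n_classes)
  for (k in seq_len(n_classes)) {
    avg <- km$centers[k, ]
    avg <- avg - mean(avg)
    cc <- vapply(tfeat, function(t_) {
      t_ <- t_ - mean(t_)
      sum(avg * t_) / sqrt(sum(avg^2) * sum(t_^2))
    }, 0)
    class_map[k] <- names(tfeat)[which.max(cc)]
  }
  list(class_of = km$cluster, class_map = class_map,
       labels = class_map[km$cluster])
}

#' Consensus morphology percentages over classification runs
#'
#' The multi-run consensus: per run and per condition/replicate group, the
#' percentage of particles in classes mapped to each morphology (the three
#' percentages sum to 100 within each run); then the mean and sample s.d.
#' of each percentage across runs. Percentages are invariant to run and
#' particle order, and to merging two classes with the same morphology.
#'
#' @param runs List of runs, each a list with `class_of` (class id per
#'   particle) and `class_map` (morphology per class id), e.g. from
#'   [run_morphology_classification()]. All runs must cover the same
#'   particles.
#' @param groups Optional vector of group labels per particle (condition x
#'   replicate); a single pooled group by default.
#' @return Data.frame with `group`, `morphology`, `mean_percent`,
#'   `sd_percent`, `n_runs`.
#' @export
consensus_percentages <- function(runs, groups = NULL) {
  stopifnot(length(runs) >= 1L)
  n <- length(runs[[1L]]$class_of)
  morphs <- c("cofilactin", "factin", "other")
  if (is.null(groups)) groups <- rep("all", n)
  stopifnot(length(groups) == n)
  glev <- unique(groups)
  per_run <- array(NA_real_, c(length(runs), length(glev), length(morphs)),
                   dimnames = list(NULL, as.character(glev), morphs))
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    if (length(run$class_of) != n)
      stop("run ", r, " does not cover the same particle set")
    lab <- run$class_map[run$class_of]
    if (anyNA(lab)) stop("run ", r, " has classes without a morphology mapping")
    for (g in seq_along(glev)) {
      sel <- groups == glev[g]
      for (m in seq_along(morphs))
        per_run[r, g, m] <- 100 * sum(lab[sel] == morphs[m]) / sum(sel)
    }
  }
  out <- expand.grid(group = glev, morphology = morphs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_percent <- mapply(function(g, m) mean(per_run[, as.character(g), m]),
                             out$group, out$morphology)
  out$sd_percent <- mapply(function(g, m) {
    v <- per_run[, as.character(g), m]
    if (length(v) > 1L) stats::sd(v) else NA_real_
  }, out$group, out$morphology)
  out$n_runs <- length(runs)
  out
}

#' The standard nine-run consensus protocol
#'
#' Convenience wrapper running the full protocol: classifications with 5,
#' 10 and 20 classes, each at reference twists -162, -165 and -167 degrees
#' (nine runs), followed by [consensus_percentages()].
#'
#' @param images Array `ny x nz x n` of particle images.
#' @param apix Pixel size, Angstrom.
#' @param groups Optional group labels per particle.
#' @param class_counts,ref_twists Run grid (defaults are the protocol's).
#' @param seed Base seed; each run derives its own stream from it.
#' @return List with `consensus` (data.frame) and `runs`.
#' @export
morphology_consensus <- function(images, apix = 11.81, groups = NULL,
                                 class_counts = c(5L, 10L, 20L),
                                 ref_twists = c(-162, -165, -167),
                                 seed = 1L) {
  d <- dim(images)
  templates <- morphology_templates(box = d[1:2], apix = apix)
  runs <- list()
  r <- 0L
  for (k in class_counts) for (tw in ref_twists) {
    r <- r + 1L
    runs[[r]] <- run_morphology_classification(
      images, n_classes = k, templates = templates,
      seed = seed + 1000L * r)
  }
  list(consensus = consensus_percentages(runs, groups), runs = runs)
}
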