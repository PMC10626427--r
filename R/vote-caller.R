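#' Assignment rule for the classification-vote caller
#'
#' The thresholds of the per-filament assignment algorithm: first the
#' particle table is cleaned by keeping the best-scoring `keep_fraction`
#' of particles, then a filament is assigned to its modal class if that
#' class holds at least `f_major` of its retained particles, or at least
#' `f_minor` with the filament's overall cross-correlation score at or
#' above `cc_min`. Filaments meeting neither criterion stay undetermined
#' and are excluded from all quantifications.
#'
#' @param keep_fraction Fraction of particles retained by cc cleaning.
#' @param f_major Majority-vote threshold (no cc condition).
#' @param f_minor Minority-vote threshold (requires the cc condition).
#' @param cc_min Minimum overall cc score for the minority criterion.
#' @param cc_stat How the filament's overall cc is summarized from its
#'   retained particles: `"mean"` (default) or `"median"`.
#' @param clean_scope `"global"` (clean across the whole table, default)
#'   or `"per_filament"`.
#' @return Object of class `assignment_rule`.
#' @export
assignment_rule <- function(keep_fraction = 0.80, f_major = 0.65,
                            f_minor = 0.50, cc_min = 0.13,
                            cc_stat = c("mean", "median"),
                            clean_scope = c("global", "per_filament")) {
  cc_stat <- match.arg(cc_stat)
  clean_scope <- match.arg(clean_scope)
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must lie in (0, 1]")
  if (!(f_minor >= 0.5 && f_minor <= f_major && f_major <= 1))
    stop("need 0.5 <= f_minor <= f_major <= 1")
  structure(list(keep_fraction = keep_fraction, f_major = f_major,
                 f_minor = f_minor, cc_min = cc_min, cc_stat = cc_stat,
                 clean_scope = clean_scope),
            class = "assignment_rule")
}

#' Clean a particle table by cross-correlation score
#'
#' Retains the top `ceil(keep_fraction * n)` particles by cc score. By
#' default cleaning is global across the table; ties are broken stably by
#' (cc descending, particle_id ascending), so among equal scores the
#' lowest ids are retained first.
#'
#' @param table Particle data.frame with columns `particle_id`,
#'   `filament_id`, `cc`.
#' @param rule An [assignment_rule()].
#' @return The retained subset of `table` (original row order).
#' @export
clean_by_cc <- function(table, rule = assignment_rule()) {
  if (nrow(table) == 0L) stop("empty particle table")
  keep_top <- function(df) {
    k <- ceiling(rule$keep_fraction * nrow(df))
    ord <- order(-df$cc, df$particle_id)
    df[sort(ord[seq_len(k)]), , drop = FALSE]
  }
  if (rule$clean_scope == "global") return(keep_top(table))
  out <- do.call(rbind, lapply(split(table, table$filament_id), keep_top))
  out[order(match(out$particle_id, table$particle_id)), , drop = FALSE]
}

#' Call one filament's class from its particle votes
#'
#' The winning class is the modal vote among the filament's retained
#' particles. The filament is assigned to it if the winning fraction
#' reaches `f_major`, or reaches `f_minor` with the filament's overall cc
#' score at or above `cc_min`. An exact modal tie is undetermined (the
#' criteria cannot distinguish the tied classes).
#'
#' @param particles Data.frame of one filament's retained particles, with
#'   columns `class_label` and `cc`.
#' @param rule An [assignment_rule()].
#' @return List with `class` (label or `NA`), `assigned`, `fraction` (of
#'   the modal class) and `cc_score` (the filament's overall cc).
#' @export
call_filament <- function(particles, rule = assignment_rule()) {
  n <- nrow(particles)
  if (is.null(n) || n == 0L)
    return(list(class = NA_character_, assigned = FALSE,
                fraction = NA_real_, cc_score = NA_real_))
  counts <- table(particles$class_label)
  top <- max(counts)
  winners <- names(counts)[counts == top]
  frac <- top / n
  cc_score <- if (rule$cc_stat == "mean") mean(particles$cc)
              else stats::median(particles$cc)
  if (length(winners) > 1L)
    return(list(class = NA_character_, assigned = FALSE,
                fraction = frac, cc_score = cc_score))
  assigned <- frac >= rule$f_major ||
    (frac >= rule$f_minor && cc_score >= rule$cc_min)
  list(class = if (assigned) winners else NA_character_,
       assigned = assigned, fraction = frac, cc_score = cc_score)
}

#' Call every filament in a (cleaned) particle table
#'
#' Applies [call_filament()] per filament. Filaments present in `all_ids`
#' but emptied by cleaning are reported undetermined.
#'
#' @param table Cleaned particle data.frame.
#' @param rule An [assignment_rule()].
#' @param all_ids Optional vector of all filament ids (to keep filaments
#'   whose every particle was removed by cleaning).
#' @return Data.frame with one row per filament: `filament_id`,
#'   `protrusion_id` (if present), `class`, `assigned`, `fraction`,
#'   `cc_score`, `n_particles`.
#' @export
call_filaments <- function(table, rule = assignment_rule(), all_ids = NULL) {
  ids <- unique(c(table$filament_id, all_ids))
  rows <- lapply(ids, function(id) {
    part <- table[table$filament_id == id, , drop = FALSE]
    cl <- call_filament(part, rule)
    data.frame(filament_id = id,
               protrusion_id = if ("protrusion_id" %in% names(part) &&
                                   nrow(part)) part$protrusion_id[1L] else NA,
               class = cl$class, assigned = cl$assigned,
               fraction = cl$fraction, cc_score = cl$cc_score,
               n_particles = nrow(part), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a class label into protofilament number and polarity
#'
#' Class labels are `"N:polarity"` strings (e.g. `"13:plus"`).
#'
#' @param class Character vector of class labels.
#' @return Data.frame with `n_pf` (integer) and `polarity`.
#' @export
split_class_label <- function(class) {
  parts <- strsplit(as.character(class), ":", fixed = TRUE)
  data.frame(n_pf = as.integer(vapply(parts, `[`, "", 1L)),
             polarity = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Summarize microtubule calls per protrusion
#'
#' A protrusion's microtubule orientation is `uniform` when all its
#' assigned microtubules share one polarity, `mixed` otherwise; protrusions
#' with fewer than 2 assigned microtubules are `excluded`. The
#' protofilament mix is `single` or `mixed` by the number of distinct
#' protofilament classes among assigned microtubules.
#'
#' @param calls Data.frame from [call_filaments()], with `protrusion_id`.
#' @return Data.frame with one row per protrusion: `protrusion_id`,
#'   `n_assigned`, `orientation`, `pf_mix`.
#' @export
summarize_protrusions <- function(calls) {
  stopifnot("protrusion_id" %in% names(calls))
  out <- lapply(split(calls, calls$protrusion_id), function(g) {
    a <- g[g$assigned, , drop = FALSE]
    if (nrow(a) < 2L)
      return(data.frame(protrusion_id = g$protrusion_id[1L],
                        n_assigned = nrow(a), orientation = "excluded",
                        pf_mix = NA_character_, stringsAsFactors = FALSE))
    lab <- split_class_label(a$class)
    data.frame(protrusion_id = g$protrusion_id[1L], n_assigned = nrow(a),
               orientation = if (length(unique(lab$polarity)) == 1L) "uniform"
                             else "mixed",
               pf_mix = if (length(unique(lab$n_pf)) >= 2L) "mixed"
                        else "single",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unify particle polarity from filament calls
#'
#' Particles of filaments called `minus` are flipped by a 180-degree
#' rotation about their second Euler axis ([flip_polarity()]), applied to
#' the particles' original orientations (kept in `rot0`/`tilt0`/`psi0`
#' columns, created on first use) — so the operation is idempotent.
#' Particles of undetermined filaments are dropped.
#'
#' @param table Particle data.frame with Euler columns `rot`, `tilt`, `psi`.
#' @param calls Data.frame from [call_filaments()].
#' @return The unified particle table.
#' @export
unify_polarity <- function(table, calls) {
  if (!all(c("rot0", "tilt0", "psi0") %in% names(table))) {
    table$rot0 <- table$rot; table$tilt0 <- table$tilt; table$psi0 <- table$psi
  }
  idx <- match(table$filament_id, calls$filament_id)
  if (anyNA(idx)) stop("every particle's filament must have a call")
  keep <- calls$assigned[idx]
  table <- table[keep, , drop = FALSE]
  idx <- idx[keep]
  pol <- split_class_label(calls$class[idx])$polarity
  table$rot <- table$rot0; table$tilt <- table$tilt0; table$psi <- table$psi0
  flip_rows <- which(pol == "minus")
  for (i in flip_rows) {
    e <- flip_polarity(c(table$rot0[i], table$tilt0[i], table$psi0[i]))
    table$rot[i] <- e[["rot"]]; table$tilt[i] <- e[["tilt"]]
    table$psi[i] <- e[["psi"]]
  }
  table
}

#' Protofilament-number distribution of assigned microtubules
#'
#' Per group (e.g. replicate, or replicate x luminal occupancy), the
#' fraction of assigned microtubules with each protofilament number in
#' 12..15; undetermined filaments are excluded. When several groups are
#' present, cross-group mean and sample s.d. (n-1) of each percentage are
#' reported alongside.
#'
#' @param calls Data.frame from [call_filaments()].
#' @param groups Optional vector (same length as `nrow(calls)`) of group
#'   labels; a single group by default.
#' @return List with `per_group` (group x n_pf percentage matrix; groups
#'   with no assigned filament are flagged `NA`) and `summary`
#'   (data.frame: n_pf, mean_percent, sd_percent).
#' @export
pf_distribution <- function(calls, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(calls))
  stopifnot(length(groups) == nrow(calls))
  glev <- unique(groups)
  pf_lev <- 12:15
  per_group <- matrix(NA_real_, length(glev), length(pf_lev),
                      dimnames = list(as.character(glev), as.character(pf_lev)))
  for (g in seq_along(glev)) {
    a <- calls[groups == glev[g] & calls$assigned, , drop = FALSE]
    if (nrow(a) == 0L) next  # flagged: stays NA
    npf <- split_class_label(a$class)$n_pf
    per_group[g, ] <- 100 * vapply(pf_lev, function(p) mean(npf == p), 0)
  }
  summary <- data.frame(
    n_pf = pf_lev,
    mean_percent = colMeans(per_group, na.rm = TRUE),
    sd_percent = apply(per_group, 2, function(v) stats::sd(v[!is.na(v)])))
  rownames(summary) <- NULL
  list(per_group = per_group, summary = summary)
}
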