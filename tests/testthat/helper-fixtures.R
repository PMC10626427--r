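# Shared fixtures, built lazily once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

cofilactin_sym <- function() helical_symmetry(-161.8, 28.5)
factin_sym <- function() helical_symmetry(-167, 27.5)

# 64^3 noiseless filament maps at ~5.9 A/voxel for symmetry searches
cof_map64 <- function() cached("cof_map64", function()
  render_helical_filament(cofilactin_sym(), box = 64, apix = 5.9,
                          morphology = "cofilactin"))
factin_map64 <- function() cached("factin_map64", function()
  render_helical_filament(factin_sym(), box = 64, apix = 5.9,
                          morphology = "factin"))

# ~600 nm filament at bin4 sampling for cross-over measurement
cof_filament_bin4 <- function() cached("cof_filament_bin4", function()
  render_helical_filament(cofilactin_sym(), box = c(48, 48, 512),
                          apix = 11.81, morphology = "cofilactin"))

# protofilament-number class fractions over (N, polarity) classes, split
# evenly by polarity
pf_class_fractions <- function(p12 = 0.028, p13 = 0.933, p14 = 0.036,
                               p15 = 0.003) {
  f <- c(p12, p13, p14, p15) / sum(p12, p13, p14, p15)
  stats::setNames(rep(f / 2, each = 2),
                  paste0(rep(12:15, each = 2), c(":plus", ":minus")))
}

# straight trace along z at (x, y), nm
straight_trace <- function(id, x, y, z0 = 5, z1 = 51, n = 10,
                           kind = "microtubule")
  filament_trace(cbind(x, y, seq(z0, z1, length.out = n)), id = id, kind = kind)

# independent re-derivation of the filament-call rule, written as a per-class
# qualification check rather than a modal-vote computation
oracle_call <- function(labels, cc, f_major = 0.65, f_minor = 0.50,
                        cc_min = 0.13) {
  n <- length(labels)
  cc_score <- sum(cc) / n
  qualified <- character()
  for (cl in unique(labels)) {
    n_cl <- 0L
    for (l in labels) if (l == cl) n_cl <- n_cl + 1L
    strictly_modal <- TRUE
    for (other in unique(labels))
      if (other != cl && sum(labels == other) >= n_cl) strictly_modal <- FALSE
    meets <- (n_cl / n >= f_major) ||
             (n_cl / n >= f_minor && cc_score >= cc_min)
    if (strictly_modal && meets) qualified <- c(qualified, cl)
  }
  if (length(qualified) == 1L) qualified else NA_character_
}
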