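#' Luminal-filament occupancy per group
#'
#' Percentage of microtubules containing at least one luminal filament; a
#' microtubule hosting several filaments counts once.
#'
#' @param mt_ids Data.frame with `mt_id` and optional grouping columns
#'   (e.g. `replicate`, `condition`), one row per microtubule.
#' @param records Data.frame of luminal records with `host_mt`.
#' @param group_by Character vector of grouping column names in `mt_ids`
#'   (default: single pooled group).
#' @return Data.frame with the group columns, `n_mt`, `n_occupied`,
#'   `percent`; a group with no microtubules is undefined and flagged
#'   with `NA`.
#' @export
occupancy <- function(mt_ids, records, group_by = NULL) {
  stopifnot(is.data.frame(mt_ids), "mt_id" %in% names(mt_ids))
  if (nrow(mt_ids) == 0L) stop("empty microtubule set: occupancy undefined")
  if (nrow(records) && !all(records$host_mt %in% mt_ids$mt_id))
    stop("every record's host must be in the microtubule set")
  key <- if (is.null(group_by)) rep("all", nrow(mt_ids))
         else interaction(mt_ids[group_by], drop = TRUE)
  occ <- mt_ids$mt_id %in% unique(records$host_mt)
  out <- do.call(rbind, lapply(split(seq_len(nrow(mt_ids)), key), function(i) {
    g <- if (is.null(group_by)) data.frame(group = "all")
         else unique(mt_ids[i, group_by, drop = FALSE])
    cbind(g, data.frame(n_mt = length(i), n_occupied = sum(occ[i]),
                        percent = 100 * mean(occ[i])))
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of a microtubule's length covered by luminal filaments
#'
#' Summed filament length divided by the microtubule length, clamped to 1.
#' A coverage of 0 means no filaments; 1 means the whole microtubule is
#' covered. A summed length exceeding the microtubule by more than 5%
#' indicates a tracing inconsistency and raises a warning before clamping.
#'
#' @param mt_length Microtubule length, nm (> 0).
#' @param filament_lengths Lengths (nm) of the filaments inside it.
#' @return Coverage fraction in [0, 1].
#' @export
coverage_fraction <- function(mt_length, filament_lengths = numeric()) {
  if (!(mt_length > 0)) stop("mt_length must be > 0")
  if (length(filament_lengths) == 0L) return(0)
  s <- sum(filament_lengths)
  if (s > 1.05 * mt_length)
    warning(sprintf("summed filament length (%.1f nm) exceeds microtubule (%.1f nm) by > 5%%: clamping coverage to 1",
                    s, mt_length))
  min(1, s / mt_length)
}

#' Orientation concordance of luminal filaments with their microtubule
#'
#' Fraction of filaments whose barbed (plus) end points towards the plus
#' end of the surrounding microtubule.
#'
#' @param records Data.frame with a `filament_polarity` column taking
#'   values `"towards-plus"` / `"towards-minus"`.
#' @return List with `fraction` (in [0, 1]) and `n`; both `NA` when no
#'   record has a resolved polarity pair.
#' @export
orientation_concordance <- function(records) {
  pol <- records$filament_polarity
  pol <- pol[!is.na(pol)]
  if (length(pol) == 0L) return(list(fraction = NA_real_, n = 0L))
  list(fraction = mean(pol == "towards-plus"), n = length(pol))
}

#' Percentage of luminal-filament length with cofilactin morphology
#'
#' Filaments may transition between morphologies along their length, so
#' the input is per-segment: each row one morphology stretch. Per group,
#' 100 x (summed cofilactin segment length) / (summed total length); with
#' several groups, the cross-group mean and sample s.d.
#'
#' @param segments Data.frame with `morphology` (`"cofilactin"`,
#'   `"factin"`, `"other"`), `length_nm`, and optional grouping columns.
#' @param group_by Character vector of grouping column names.
#' @return List with `per_group` (data.frame: group columns, `percent`)
#'   and `summary` (mean, sd, n over groups).
#' @export
morphology_length_fraction <- function(segments, group_by = NULL) {
  key <- if (is.null(group_by)) rep("all", nrow(segments))
         else interaction(segments[group_by], drop = TRUE)
  per_group <- do.call(rbind, lapply(split(seq_len(nrow(segments)), key),
    function(i) {
      tot <- sum(segments$length_nm[i])
      if (tot <= 0) stop("zero total length: fraction undefined")
      cof <- sum(segments$length_nm[i][segments$morphology[i] == "cofilactin"])
      g <- if (is.null(group_by)) data.frame(group = "all")
           else unique(segments[i, group_by, drop = FALSE])
      cbind(g, data.frame(percent = 100 * cof / tot))
    }))
  rownames(per_group) <- NULL
  list(per_group = per_group,
       summary = replicate_summary(per_group$percent))
}

#' Mean and sample standard deviation across replicates
#'
#' The summary pattern used for every per-replicate percentage: mean with
#' the (n-1)-denominator s.d.; a single replicate has an undefined s.d.,
#' reported as `NA`.
#'
#' @param values Numeric vector, one value per replicate.
#' @return List with `mean`, `sd` and `n`.
#' @export
replicate_summary <- function(values) {
  if (length(values) < 1L) stop("need at least one replicate")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}
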