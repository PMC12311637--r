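#' Resolve ASVs shared between the pico and nano protist fractions
#'
#' ASVs detected in both size fractions usually reflect cell dislodging or
#' filter clogging rather than genuine dual occupancy. For each shared ASV
#' the ratio of its mean relative abundance in the nano fraction to that in
#' the pico fraction is computed over all samples; a ratio above 2 removes
#' the ASV from the pico table, a ratio below 0.5 removes it from the nano
#' table, and intermediate ratios keep it in both. The inequalities are
#' strict, so ratios of exactly 2 or exactly 0.5 are retained in both
#' fractions.
#'
#' A pico-fraction mean of zero with a positive nano mean is treated as an
#' infinite ratio (removed from pico); an ASV with zero mean in both
#' fractions is left untouched.
#'
#' @param pico,nano [asv_table()] objects sharing the same sample set.
#'   Counts are converted to relative abundances internally; the returned
#'   tables keep the input scale.
#' @return A list with elements `pico`, `nano` (filtered tables) and
#'   `report`, a data.frame with one row per shared ASV: `asv`, `mean_pico`,
#'   `mean_nano`, `ratio`, `action` (`"drop_pico"`, `"drop_nano"`, `"keep"`).
#'   The report carries attribute `ratio_definition` documenting that the
#'   ratio is computed on across-sample mean relative abundances.
#' @export
resolve_shared_asvs <- function(pico, nano) {
  stopifnot(inherits(pico, "asv_table"), inherits(nano, "asv_table"))
  if (!setequal(rownames(pico$counts), rownames(nano$counts)))
    stop("pico and nano tables must share the same sample set")
  ord <- rownames(pico$counts)
  rel <- function(tab) {
    m <- tab$counts[ord, , drop = FALSE]
    rs <- if (tab$type == "relative") rep(1, length(ord))
    else sample_totals(tab)[ord]
    m / ifelse(rs == 0, 1, rs)
  }
  rp <- rel(pico)
  rn <- rel(nano)

  shared <- intersect(colnames(rp), colnames(rn))
  report <- data.frame(asv = character(), mean_pico = numeric(),
                       mean_nano = numeric(), ratio = numeric(),
                       action = character(), stringsAsFactors = FALSE)
  drop_p <- character()
  drop_n <- character()
  for (a in shared) {
    mp <- mean(rp[, a])
    mn <- mean(rn[, a])
    if (mp == 0 && mn == 0) {
      ratio <- NA_real_
      action <- "keep"
    } else if (mp == 0) {
      ratio <- Inf
      action <- "drop_pico"
    } else {
      ratio <- mn / mp
      action <- if (ratio > 2) "drop_pico" else if (ratio < 0.5) "drop_nano" else "keep"
    }
    if (action == "drop_pico") drop_p <- c(drop_p, a)
    if (action == "drop_nano") drop_n <- c(drop_n, a)
    report <- rbind(report, data.frame(asv = a, mean_pico = mp, mean_nano = mn,
                                       ratio = ratio, action = action,
                                       stringsAsFactors = FALSE))
  }
  attr(report, "ratio_definition") <-
    "mean relative abundance over all samples, nano / pico; strict > 2 and < 0.5"
  pico <- subset_asvs(pico, setdiff(colnames(pico$counts), drop_p))
  nano <- subset_asvs(nano, setdiff(colnames(nano$counts), drop_n))
  list(pico = pico, nano = nano, report = report)
}

#' Select ASVs eligible for network inference
#'
#' Retains ASVs that are (a) present in at least one sample of every season,
#' (b) present in strictly more than `min_prevalence_fraction` of all
#' samples, and (c) have mean relative abundance across samples strictly
#' greater than `min_mean_relabund`. Column order is preserved and the
#' surviving columns are not renormalized, so the thresholds always refer to
#' relative abundance on the original whole-community scale.
#'
#' @param table an [asv_table()] in relative-abundance form (counts are
#'   converted internally for the thresholds; the returned table keeps the
#'   input scale).
#' @param min_prevalence_fraction minimum fraction of samples an ASV must
#'   occur in (strict inequality). Default 1/3.
#' @param min_mean_relabund minimum mean relative abundance (strict).
#'   Default 0.001.
#' @param require_all_seasons if `TRUE` (default) ASVs must be detected in
#'   every season present in `sample_data$season`.
#' @return The filtered [asv_table()].
#' @export
select_network_asvs <- function(table, min_prevalence_fraction = 1 / 3,
                                min_mean_relabund = 0.001,
                                require_all_seasons = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  if (require_all_seasons &&
      (is.null(table$sample_data) || is.null(table$sample_data$season)))
    stop("season metadata required for network ASV selection")
  rel <- relative_abundance(table)$counts
  n <- nrow(rel)
  present <- rel > 0
  prevalence_ok <- colSums(present) > n * min_prevalence_fraction
  abund_ok <- colMeans(rel) > min_mean_relabund
  if (require_all_seasons) {
    season <- as.character(table$sample_data$season)
    seasons <- unique(season)
    season_ok <- Reduce(`&`, lapply(seasons, function(s)
      colSums(present[season == s, , drop = FALSE]) > 0))
  } else {
    season_ok <- rep(TRUE, ncol(rel))
  }
  subset_asvs(table, colnames(rel)[prevalence_ok & abund_ok & season_ok])
}
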