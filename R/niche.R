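#' Levins' niche breadth per ASV within seasonal metacommunities
#'
#' For each metacommunity (by default the set of samples of one season) and
#' each ASV j present there, `B_j = 1 / sum_i P_ij^2`, where `P_ij` is the
#' proportion of ASV j's metacommunity total found in community (sample) i.
#' B ranges from 1 (restricted to a single community: a specialist) to N,
#' the number of communities in the metacommunity (evenly spread: a
#' generalist). ASVs absent from a metacommunity are undefined there and
#' reported separately.
#'
#' @param table an [asv_table()] (counts or relative abundances; B is
#'   invariant to rescaling an ASV's abundances).
#' @param grouping vector of metacommunity labels, one per sample; defaults
#'   to `sample_data$season`.
#' @return object of class `niche_breadth`: list with `breadth` (data.frame
#'   `asv`, `metacommunity`, `B`, `N`), `absent` (ASVs undefined per
#'   metacommunity) and `grouping`.
#' @export
levins_breadth <- function(table, grouping = NULL) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(grouping)) {
    if (is.null(table$sample_data) || is.null(table$sample_data$season))
      stop("no grouping given and no season metadata present")
    grouping <- table$sample_data$season
  }
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(table$counts))
    stop("one metacommunity label per sample required")
  out <- list()
  absent <- list()
  for (g in unique(grouping)) {
    sub <- table$counts[grouping == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty metacommunity: ", g)
    tot <- colSums(sub)
    present <- tot > 0
    b <- rep(NA_real_, ncol(sub))
    if (any(present)) {
      pm <- sweep(sub[, present, drop = FALSE], 2, tot[present], "/")
      b[present] <- 1 / colSums(pm^2)
    }
    out[[g]] <- data.frame(asv = colnames(sub)[present],
                           metacommunity = g, B = b[present],
                           N = nrow(sub), stringsAsFactors = FALSE)
    absent[[g]] <- colnames(sub)[!present]
  }
  structure(list(breadth = do.call(rbind, out), absent = absent,
                 grouping = grouping,
                 counts = table$counts), class = "niche_breadth")
}

#' Community-level niche breadth
#'
#' For each community (sample), the unweighted arithmetic mean of Levins'
#' B over the ASVs present (abundance > 0) in that sample, each ASV's B
#' taken from the sample's own metacommunity. An abundance-weighted mean is
#' available via `weighted = TRUE`. Samples with no ASVs get NA.
#'
#' @param result a `niche_breadth` from [levins_breadth()].
#' @param weighted if `TRUE`, weight each ASV's B by its relative abundance
#'   in the sample instead of the plain mean.
#' @return data.frame with columns `sample`, `metacommunity`,
#'   `mean_breadth`, `n_asvs`.
#' @export
community_level_breadth <- function(result, weighted = FALSE) {
  stopifnot(inherits(result, "niche_breadth"))
  counts <- result$counts
  grouping <- result$grouping
  b_lookup <- split(setNames(result$breadth$B, result$breadth$asv),
                    result$breadth$metacommunity)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    g <- grouping[i]
    x <- counts[i, ]
    present <- names(x)[x > 0]
    bs <- b_lookup[[g]][present]
    bs <- bs[!is.na(bs)]
    mb <- if (length(bs) == 0) NA_real_
    else if (weighted) {
      w <- x[names(bs)] / sum(x[names(bs)])
      sum(w * bs)
    } else mean(bs)
    data.frame(sample = rownames(counts)[i], metacommunity = g,
               mean_breadth = mb, n_asvs = length(bs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
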