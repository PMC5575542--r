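# Substitution-enrichment tests: four-category site counts between the ML
# ancestral sequences at either end of a phylogenetic window, Fisher's exact
# test per structural region, and the OR > 1.5 & p < .05 significance rule.

#' Four-category substitution counts between two ancestral sequences
#'
#' Sites where either sequence has a gap are excluded; remaining sites are
#' cross-classified as substituted (symbols differ) x in-region.
#'
#' @param seq_start,seq_end Character vectors of equal length (alignment
#'   coordinates, `"-"` gaps) or single strings.
#' @param region_columns Integer set of in-region columns (1-based).
#' @return Object of class `contingency_table`: list with `a` (substituted,
#'   in-region), `b` (unsubstituted, in-region), `c` (substituted,
#'   out-of-region), `d` (unsubstituted, out-of-region), `excluded`.
#' @export
count_substitutions <- function(seq_start, seq_end, region_columns) {
  if (length(seq_start) == 1 && nchar(seq_start[1]) > 1)
    seq_start <- strsplit(seq_start, "")[[1]]
  if (length(seq_end) == 1 && nchar(seq_end[1]) > 1)
    seq_end <- strsplit(seq_end, "")[[1]]
  if (length(seq_start) != length(seq_end))
    stop_pe("input_error", "sequences must have equal length (%d vs %d)",
            length(seq_start), length(seq_end))
  L <- length(seq_start)
  gap <- seq_start == GAP_CHAR | seq_end == GAP_CHAR
  sub <- seq_start != seq_end & !gap
  inreg <- seq_len(L) %in% region_columns
  tab <- list(a = sum(sub & inreg & !gap),
              b = sum(!sub & inreg & !gap),
              c = sum(sub & !inreg & !gap),
              d = sum(!sub & !inreg & !gap),
              excluded = sum(gap))
  class(tab) <- "contingency_table"
  tab
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table: a=%d b=%d c=%d d=%d (excluded %d)>\n",
              x$a, x$b, x$c, x$d, x$excluded))
  invisible(x)
}

as_table_counts <- function(table) {
  if (inherits(table, "contingency_table"))
    c(table$a, table$b, table$c, table$d)
  else as.numeric(table)[1:4]
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Exact hypergeometric tail.  Two-sided: sum of probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed one (with the conventional tiny relative slack);
#' `"greater"`: right tail on the in-region substituted count.
#'
#' @param table A [count_substitutions()] result or numeric `(a, b, c, d)`.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  x <- as_table_counts(table)
  if (any(x < 0)) stop_pe("input_error", "counts must be >= 0")
  if (sum(x) == 0) {
    warning("all-zero table; p = 1")
    return(1)
  }
  m <- matrix(x, nrow = 2, byrow = TRUE)
  fisher.test(m, alternative = alternative)$p.value
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; `+Inf` when only the denominator product is zero, `NA`
#' when both products are zero.  Haldane's +0.5 correction available behind
#' a flag (off by default).
#'
#' @param table A [count_substitutions()] result or numeric `(a, b, c, d)`.
#' @param haldane Add 0.5 to every cell first.
#' @return Numeric (possibly `Inf` or `NA`).
#' @export
odds_ratio <- function(table, haldane = FALSE) {
  x <- as_table_counts(table)
  if (haldane) x <- x + 0.5
  num <- x[1] * x[4]
  den <- x[2] * x[3]
  if (den == 0 && num == 0) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

#' Resolve named ancestors and form phylogenetic windows
#'
#' Each ancestor is the MRCA of its taxon set; windows connect consecutive
#' ancestors ordered from the root towards the tips, and each window's
#' start must be ancestral to its end.
#'
#' @param tree Rooted `phylo` with internal labels.
#' @param ancestor_specs Named list: ancestor name -> character vector of
#'   tip labels whose MRCA defines it.
#' @return data.frame with columns `name`, `start`, `end`, `start_node`,
#'   `end_node` (node labels).
#' @export
define_windows <- function(tree, ancestor_specs) {
  tree <- ensure_node_labels(tree)
  if (length(ancestor_specs) < 2)
    stop_pe("window_error", "need at least two ancestors")
  ids <- vapply(names(ancestor_specs), function(nm) {
    taxa <- ancestor_specs[[nm]]
    if (length(taxa) == 0)
      stop_pe("window_error", "ancestor '%s' has an empty taxon set", nm)
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop_pe("window_error", "ancestor '%s': unknown taxa %s", nm,
              paste(missing, collapse = " "))
    if (length(taxa) == 1) match(taxa, tree$tip.label)
    else ape::getMRCA(tree, taxa)
  }, numeric(1))
  # order from root to tips by clade size (root-most ancestor first)
  sizes <- vapply(ids, function(i) length(clade_ids(tree, i)), numeric(1))
  ord <- order(-sizes)
  ids <- ids[ord]
  nms <- names(ancestor_specs)[ord]
  rows <- lapply(seq_len(length(ids) - 1), function(i) {
    s <- ids[i]
    e <- ids[i + 1]
    if (!(e %in% clade_ids(tree, s)) || s == e)
      stop_pe("window_error",
              "'%s' is not ancestral to '%s'; windows must follow one root-to-tip path",
              nms[i], nms[i + 1])
    data.frame(name = paste0(nms[i], "..", nms[i + 1]),
               start = nms[i], end = nms[i + 1],
               start_node = node_label(tree, s),
               end_node = node_label(tree, e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Enrichment scan over all (region, window) combinations
#'
#' For every window, the ML ancestral sequences at its two endpoints are
#' compared and each region is tested for substitution enrichment with
#' Fisher's exact test.  A combination is flagged significant iff its odds
#' ratio strictly exceeds `or_threshold` and its p-value is strictly below
#' `p_threshold` (no multiple-testing correction, though a
#' Benjamini-Hochberg column is reported).
#'
#' @param recon An `ancestral_reconstruction`, or a named list of ancestor
#'   sequences (character vectors with `"-"` gaps) keyed by node label.
#' @param windows A [define_windows()] data.frame (columns `name`,
#'   `start_node`, `end_node`).
#' @param region_map A [region_map()].
#' @param or_threshold,p_threshold Significance thresholds (defaults 1.5
#'   and .05, strict inequalities).
#' @param alternative Sidedness of [fisher_exact()].
#' @param gap_policy `"exclude"` (drop sites where either endpoint is
#'   absent) or `"substitution"` (count presence changes as substitutions;
#'   sites absent at both ends are still excluded).
#' @return data.frame, one row per (window, region): counts, `excluded`,
#'   `odds_ratio`, `p_value`, `bh_q`, `significant`.  Windows whose
#'   endpoint sequences are unavailable are skipped and recorded in the
#'   `"skipped"` attribute.
#' @export
enrichment_scan <- function(recon, windows, region_map,
                            or_threshold = 1.5, p_threshold = 0.05,
                            alternative = "two.sided",
                            gap_policy = c("exclude", "substitution")) {
  gap_policy <- match.arg(gap_policy)
  seqs <- if (inherits(recon, "ancestral_reconstruction")) recon$ml else recon
  stopifnot(inherits(region_map, "region_map"))
  rows <- list()
  skipped <- character()
  for (w in seq_len(nrow(windows))) {
    s <- seqs[[windows$start_node[w]]]
    e <- seqs[[windows$end_node[w]]]
    if (is.null(s) || is.null(e)) {
      skipped <- c(skipped, windows$name[w])
      next
    }
    if (gap_policy == "substitution") {
      both_gap <- s == GAP_CHAR & e == GAP_CHAR
      one_gap <- xor(s == GAP_CHAR, e == GAP_CHAR)
      s2 <- s
      e2 <- e
      # recode one-sided gaps as a guaranteed mismatch of non-gap symbols
      s2[one_gap] <- "A"
      e2[one_gap] <- "C"
      s2[both_gap] <- GAP_CHAR
      e2[both_gap] <- GAP_CHAR
      s <- s2
      e <- e2
    }
    for (rg in names(region_map$columns)) {
      tab <- count_substitutions(s, e, region_map$columns[[rg]])
      or <- odds_ratio(tab)
      p <- suppressWarnings(fisher_exact(tab, alternative))
      rows[[length(rows) + 1]] <-
        data.frame(window = windows$name[w], region = rg,
                   a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                   excluded = tab$excluded,
                   odds_ratio = or, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window = character(), region = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), excluded = integer(),
                      odds_ratio = numeric(), p_value = numeric())
  out$bh_q <- if (nrow(out)) p.adjust(out$p_value, "BH") else numeric(0)
  out$significant <- !is.na(out$odds_ratio) &
    out$odds_ratio > or_threshold & out$p_value < p_threshold
  attr(out, "skipped") <- skipped
  attr(out, "thresholds") <- list(or = or_threshold, p = p_threshold,
                                  alternative = alternative,
                                  gap_policy = gap_policy)
  out
}
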