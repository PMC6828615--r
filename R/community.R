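#' Relative abundance table
#'
#' Converts a taxa-by-section count matrix to per-section proportions. A
#' section is missing if its column is all `NA` or sums to zero; missing
#' columns come back as `NA`.
#'
#' @param table Numeric matrix, taxa in rows, sections in columns.
#' @return Matrix of the same shape; non-missing columns sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(is.matrix(table))
  cs <- colSums(table)
  cs[!is.na(cs) & cs == 0] <- NA      # all-zero column -> missing
  sweep(table, 2, cs, "/")
}

#' Which sections are missing from a count table?
#'
#' @param table Taxa-by-section count matrix.
#' @return Logical vector per column: all-`NA` or zero-sum columns.
#' @export
missing_sections <- function(table) {
  cs <- colSums(table)
  is.na(cs) | cs == 0
}

#' Richness, Shannon index, and Pielou evenness
#'
#' Richness `S` counts taxa with at least one read, `H = -sum p_i ln p_i`
#' over taxa with nonzero counts (natural log), and Pielou evenness
#' `J = H / ln S` (0 by convention when `S = 1`).
#'
#' @param table Taxa-by-section count matrix (non-negative).
#' @param level `"section"` (one row per non-missing section, default) or
#'   `"pooled"` (reads summed over non-missing sections first).
#' @param base Logarithm base (default `exp(1)`).
#' @return Data frame with columns `section_id` (or `"pooled"`),
#'   `richness`, `shannon`, `evenness`; missing sections yield `NA` rows.
#' @export
diversity_summary <- function(table, level = c("section", "pooled"),
                              base = exp(1)) {
  level <- match.arg(level)
  stopifnot(is.matrix(table), all(table[!is.na(table)] >= 0))
  one <- function(counts) {
    if (all(is.na(counts)) || sum(counts, na.rm = TRUE) == 0)
      return(c(NA_real_, NA_real_, NA_real_))
    counts <- counts[!is.na(counts) & counts > 0]
    s <- length(counts)
    p <- counts / sum(counts)
    h <- -sum(p * log(p, base = base))
    j <- if (s > 1) h / log(s, base = base) else 0
    c(s, h, j)
  }
  if (level == "pooled") {
    keep <- !missing_sections(table)
    pooled <- rowSums(table[, keep, drop = FALSE])
    v <- one(pooled)
    return(data.frame(section_id = "pooled", richness = v[1],
                      shannon = v[2], evenness = v[3],
                      stringsAsFactors = FALSE))
  }
  res <- t(apply(table, 2, one))
  data.frame(section_id = colnames(table) %||% seq_len(ncol(table)),
             richness = res[, 1], shannon = res[, 2], evenness = res[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bray-Curtis dissimilarity between two sections
#'
#' `BC = 1 - 2 * sum(min(p_i, q_i)) / (sum p + sum q)`; 0 for identical
#' composition, 1 for disjoint taxon sets.
#'
#' @param p,q Non-negative count (or proportion) vectors over the same taxa.
#' @return Dissimilarity in `[0, 1]`; `NA` (with a warning) if both
#'   sections are empty.
#' @export
bray_curtis <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(c(p, q) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  tot <- sum(p) + sum(q)
  if (is.na(tot) || tot == 0) {
    warning("both sections empty; Bray-Curtis undefined")
    return(NA_real_)
  }
  1 - 2 * sum(pmin(p, q)) / tot
}

#' Bray-Curtis dissimilarity between adjacent sections
#'
#' One record per pair of consecutive non-missing sections (missing sections
#' break adjacency: no pair spans a gap). By default counts are converted to
#' proportions first, so unequal read depths do not register as
#' dissimilarity; set `use = "counts"` for raw counts.
#'
#' @param table Taxa-by-section count matrix in section order.
#' @param use `"proportions"` (default) or `"counts"`.
#' @return Object of class `adjacent_dissimilarity`: list with `pairs`
#'   (data frame `section_a`, `section_b`, `bray_curtis`), `mean`, `sd`,
#'   `n_pairs`.
#' @export
adjacent_dissimilarity <- function(table, use = c("proportions", "counts")) {
  use <- match.arg(use)
  ok <- !missing_sections(table)
  if (sum(ok) < 2) stop("need at least 2 non-missing sections")
  m <- if (use == "proportions") relative_abundance(table) else table
  i <- which(ok[-length(ok)] & ok[-1])
  if (length(i) == 0L) stop("no adjacent non-missing section pair")
  bc <- vapply(i, function(s) bray_curtis(m[, s], m[, s + 1L]), numeric(1))
  ids <- colnames(table) %||% as.character(seq_len(ncol(table)))
  structure(list(
    pairs = data.frame(section_a = ids[i], section_b = ids[i + 1L],
                       bray_curtis = bc, stringsAsFactors = FALSE),
    mean = mean(bc), sd = stats::sd(bc), n_pairs = length(bc)
  ), class = "adjacent_dissimilarity")
}

#' @export
print.adjacent_dissimilarity <- function(x, ...) {
  cat(sprintf(
    "Adjacent-section Bray-Curtis: %.2f +/- %.2f (range %.2f-%.2f, n = %d)\n",
    x$mean, x$sd, min(x$pairs$bray_curtis), max(x$pairs$bray_curtis),
    x$n_pairs))
  invisible(x)
}

#' Dominant taxa at a share-of-total-reads threshold
#'
#' Ranks taxa by total reads pooled over non-missing sections; a taxon is
#' dominant if its share of total reads is at least `threshold`. The
#' threshold applies to the pooled table, not per section. Ties in total
#' reads are broken lexicographically by taxon label for determinism.
#'
#' @param table Taxa-by-section count matrix with taxon rownames.
#' @param threshold Minimum share of total reads (default 0.01 = 1%).
#' @return Object of class `dominance_summary`: list with `taxa` (data
#'   frame `taxon`, `total_reads`, `share_pct`, ordered by total reads),
#'   `dominant` (character vector), `cumulative_share_pct` (of the dominant
#'   set), `top_n_share_pct(n)` via [top_share()].
#' @export
dominant_taxa <- function(table, threshold = 0.01) {
  stopifnot(is.matrix(table))
  keep <- !missing_sections(table)
  totals <- rowSums(table[, keep, drop = FALSE])
  labels <- rownames(table) %||% as.character(seq_len(nrow(table)))
  ord <- order(-totals, labels)
  share <- totals / sum(totals) * 100
  df <- data.frame(taxon = labels[ord], total_reads = totals[ord],
                   share_pct = share[ord], row.names = NULL,
                   stringsAsFactors = FALSE)
  dom <- df$taxon[df$share_pct >= threshold * 100]
  structure(list(
    taxa = df,
    dominant = dom,
    threshold = threshold,
    cumulative_share_pct = sum(df$share_pct[df$taxon %in% dom])
  ), class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf(
    "%d dominant taxa (>= %.1f%% of total reads) covering %.1f%% of reads\n",
    length(x$dominant), x$threshold * 100, x$cumulative_share_pct))
  print(utils::head(x$taxa, max(5L, length(x$dominant))))
  invisible(x)
}

#' Cumulative share of the top-n taxa
#'
#' @param dominance A `dominance_summary`.
#' @param n Number of top-ranked taxa.
#' @return Cumulative share of total reads in percent.
#' @export
top_share <- function(dominance, n) {
  stopifnot(inherits(dominance, "dominance_summary"))
  sum(utils::head(dominance$taxa$share_pct, n))
}

#' Correlation between a taxon's abundance and a covariate
#'
#' Pearson correlation on sections where both series are present, e.g. a
#' taxon's relative abundance against section thickness, TCC, or richness.
#'
#' @param abundance Per-section relative abundance of one taxon.
#' @param covariate Per-section covariate, same order.
#' @return List: `pearson_r`, `r_squared`, `n`. Errors if fewer than 3
#'   aligned sections; `NA` (flagged with a warning) under zero variance.
#' @export
abundance_covariate_correlation <- function(abundance, covariate) {
  stopifnot(length(abundance) == length(covariate))
  ok <- !is.na(abundance) & !is.na(covariate)
  if (sum(ok) < 3) stop("need at least 3 aligned non-missing sections")
  x <- abundance[ok]; y <- covariate[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(pearson_r = NA_real_, r_squared = NA_real_, n = sum(ok)))
  }
  r <- stats::cor(x, y)
  list(pearson_r = r, r_squared = r^2, n = sum(ok))
}
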