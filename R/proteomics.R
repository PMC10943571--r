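#' Per-analyte association screen
#'
#' One linear model per analyte, `outcome ~ analyte (+ covariates)`, with
#' analyte values log-transformed (RFU distributions are right-skewed) and
#' column-standardized before modelling. Covariates, when given, are
#' projected out of both sides (Frisch-Waugh) with the residual degrees of
#' freedom adjusted accordingly, so the per-analyte fits stay vectorized.
#' Significance is called at raw two-sided `p <= alpha`; BH-adjusted
#' p-values are reported alongside. Direction is the sign of the slope.
#'
#' @param analytes Subjects x analytes matrix (rownames = subject ids),
#'   relative fluorescence units, finite and positive.
#' @param table Subject data frame with a `subject_id` column.
#' @param outcome Outcome column in `table`.
#' @param alpha Significance level (default 0.05).
#' @param covariates Covariate columns in `table` (default none).
#' @param log_transform Log the RFU values first (default `TRUE`).
#' @param exclude_subjects Subject ids to drop (e.g. PCA outliers).
#' @param analyte_info Optional data frame (probe_id, symbol) mapping probes
#'   to proteins; protein-level sets are deduplicated by symbol.
#' @return A `screen_result`: `results` data frame (one row per analyte),
#'   `significant`, `positive`, `negative` (probe-id sets), protein-level
#'   `positive_proteins` / `negative_proteins` / `significant_proteins`
#'   when symbols are available, `n_used`, `subjects_used`, `alpha`.
#' @export
screen <- function(analytes, table, outcome, alpha = 0.05,
                   covariates = NULL, log_transform = TRUE,
                   exclude_subjects = NULL, analyte_info = NULL) {
  stopifnot(is.matrix(analytes), !is.null(rownames(analytes)))
  if (anyDuplicated(rownames(analytes))) stop("duplicated subject ids")
  subj <- intersect(rownames(analytes), table$subject_id)
  subj <- setdiff(subj, exclude_subjects)
  if (length(subj) < 4L) stop("no (or too few) overlapping subjects")
  X <- analytes[subj, , drop = FALSE]
  if (log_transform) {
    if (any(X <= 0)) stop("RFU values must be positive for log transform")
    X <- log(X)
  }
  y <- table[[outcome]][match(subj, table$subject_id)]
  X <- scale(X)
  q <- 0L
  if (!is.null(covariates) && length(covariates)) {
    Z <- stats::model.matrix(stats::reformulate(covariates),
                             data = table[match(subj, table$subject_id), ,
                                          drop = FALSE])
    qrz <- qr(Z)
    y <- stats::residuals(stats::lm.fit(Z, y))
    X <- qr.resid(qrz, X)
    q <- qrz$rank - 1L
  }
  n <- length(y)
  yc <- y - mean(y)
  sxx <- colSums(X^2)
  sxy <- colSums(X * yc)
  beta <- sxy / sxx
  df <- n - 2L - q
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  ci <- stats::qt(0.975, df) * se
  res <- data.frame(
    probe_id = colnames(analytes),
    beta = beta, se = se, ci_low = beta - ci, ci_high = beta + ci,
    p = p, p_fdr = bh_fdr(p),
    direction = ifelse(beta >= 0, "positive", "negative"),
    row.names = NULL
  )
  res$significant <- !is.na(res$p) & res$p <= alpha
  if (!is.null(analyte_info)) {
    res$symbol <- analyte_info$symbol[match(res$probe_id, analyte_info$probe_id)]
  }
  sig <- res$probe_id[res$significant]
  pos <- res$probe_id[res$significant & res$direction == "positive"]
  neg <- res$probe_id[res$significant & res$direction == "negative"]
  out <- list(results = res, significant = sig, positive = pos, negative = neg,
              n_used = n, subjects_used = subj, alpha = alpha)
  if (!is.null(analyte_info)) {
    symof <- function(ids) unique(res$symbol[match(ids, res$probe_id)])
    out$significant_proteins <- symof(sig)
    out$positive_proteins <- symof(pos)
    out$negative_proteins <- symof(neg)
  }
  structure(out, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("<screen_result> %d/%d analytes significant at p <= %g ",
                     "(%d positive, %d negative), n = %d subjects\n"),
              length(x$significant), nrow(x$results), x$alpha,
              length(x$positive), length(x$negative), x$n_used))
  invisible(x)
}

#' PCA-based outlier detection on analyte profiles
#'
#' PCA on column-standardized (optionally log-transformed) analyte values
#' restricted to a subset of interest (e.g. the analytes associated with an
#' imaging measure); subjects whose robust Mahalanobis distance in the first
#' `k_components` score dimensions exceeds `cutoff` are flagged. The robust
#' centre/covariance is a deterministic one-step reweighted estimate
#' (classical fit, chi-square 0.975 trim, re-fit); the default cutoff is the
#' chi-square 0.999 quantile (on the distance scale), a reproducible stand-in
#' for visual "extreme loading" calls.
#'
#' @param analytes Subjects x analytes RFU matrix.
#' @param analyte_subset Probe ids to restrict to (default: all).
#' @param k_components Number of score dimensions (default 2).
#' @param cutoff Distance threshold (default `sqrt(qchisq(0.999, k))`).
#' @param log_transform Log RFU first (default `TRUE`).
#' @return Character vector of flagged subject ids (possibly empty), with
#'   the distances as attribute `distance`.
#' @export
pca_outliers <- function(analytes, analyte_subset = NULL, k_components = 2L,
                         cutoff = NULL, log_transform = TRUE) {
  stopifnot(is.matrix(analytes))
  n <- nrow(analytes)
  if (n < 3L) stop("need at least 3 subjects")
  if (k_components > n - 1L) stop("more components than subjects - 1")
  if (is.null(analyte_subset)) analyte_subset <- colnames(analytes)
  if (!length(analyte_subset)) stop("empty analyte subset")
  X <- analytes[, analyte_subset, drop = FALSE]
  if (log_transform) X <- log(X)
  X <- scale(X)
  X <- X[, apply(X, 2, function(c) all(is.finite(c))), drop = FALSE]
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(k_components, ncol(pc$x))
  S <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic one-step reweighted robust estimate: classical distances,
  # trim beyond the chi-square 0.975 quantile, re-estimate, re-measure
  d0 <- stats::mahalanobis(S, colMeans(S), stats::cov(S))
  keep <- d0 <= stats::qchisq(0.975, df = k)
  if (sum(keep) > k + 1L) {
    Sk <- S[keep, , drop = FALSE]
    d <- sqrt(stats::mahalanobis(S, colMeans(Sk), stats::cov(Sk)))
  } else {
    d <- sqrt(d0)
  }
  if (is.null(cutoff)) cutoff <- sqrt(stats::qchisq(0.999, df = k))
  flagged <- rownames(analytes)[d > cutoff]
  attr(flagged, "distance") <- stats::setNames(d, rownames(analytes))
  flagged
}

#' Read a protein-protein interaction edge list
#'
#' Three-column TSV (protein1, protein2, combined_score), STRING-export
#' compatible; scores on a 0-1000 scale are normalized to 0-1 on load.
#' Self-loops are dropped, duplicate undirected pairs collapsed (maximum
#' score kept), and edges below `min_confidence` (default 0.4, the usual
#' medium-confidence cut) removed.
#'
#' @param path TSV path.
#' @param min_confidence Minimum confidence score after normalization.
#' @return Data frame (`protein1`, `protein2`, `score`) of class
#'   `edge_list`.
#' @export
read_edge_list <- function(path, min_confidence = 0.4) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs 3 columns")
  names(df)[1:3] <- c("protein1", "protein2", "score")
  edge_list(df$protein1, df$protein2, df$score, min_confidence)
}

#' Construct an edge list in memory
#' @param protein1,protein2 Node name vectors.
#' @param score Confidence scores (0-1 or 0-1000; normalized).
#' @param min_confidence Minimum score kept (default 0.4).
#' @return `edge_list` data frame.
#' @export
edge_list <- function(protein1, protein2, score = 1, min_confidence = 0.4) {
  df <- data.frame(protein1 = as.character(protein1),
                   protein2 = as.character(protein2),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (nrow(df) && max(df$score) > 1) df$score <- df$score / 1000
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  key <- ifelse(df$protein1 < df$protein2,
                paste(df$protein1, df$protein2),
                paste(df$protein2, df$protein1))
  ord <- order(key, -df$score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[df$score >= min_confidence, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Node degrees and hub proteins of an interaction network
#'
#' Degree counts distinct neighbours (multi-edges collapsed). Hubs default
#' to the two highest-degree nodes, mirroring how highly connected proteins
#' are singled out from association networks.
#'
#' @param edges An `edge_list`.
#' @param top_n Number of hubs (default 2).
#' @return List: `degree` (named, sorted decreasing), `hubs`.
#' @export
degree_and_hubs <- function(edges, top_n = 2L) {
  if (nrow(edges) == 0L) {
    return(list(degree = stats::setNames(integer(0), character(0)),
                hubs = character(0)))
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("protein1", "protein2")], directed = FALSE))
  deg <- igraph::degree(g)
  deg <- deg[order(-deg, names(deg))]
  list(degree = deg, hubs = names(deg)[seq_len(min(top_n, length(deg)))])
}

#' Observed vs expected edge-count enrichment
#'
#' The expected edge count must be supplied (it comes from the interaction
#' database's background model, which is external). The reported one-sided
#' p-value is a Poisson upper tail on the observed count — a stand-in
#' statistic, not a reproduction of any database-internal enrichment test.
#'
#' @param edges An `edge_list`, or an observed edge count.
#' @param expected_edges Non-negative expected edge count.
#' @return List: `observed`, `expected`, `ratio`, `p`, and a `note` for the
#'   degenerate 0/0 case (reported as ratio 1).
#' @export
enrichment_vs_expected <- function(edges, expected_edges) {
  if (expected_edges < 0) stop("negative expected edge count")
  observed <- if (inherits(edges, "data.frame")) nrow(edges) else as.numeric(edges)
  if (observed == 0 && expected_edges == 0) {
    return(list(observed = 0, expected = 0, ratio = 1, p = 1,
                note = "no edges observed or expected; ratio reported as 1"))
  }
  ratio <- if (expected_edges > 0) observed / expected_edges else Inf
  p <- stats::ppois(observed - 1, lambda = expected_edges, lower.tail = FALSE)
  list(observed = observed, expected = expected_edges, ratio = ratio, p = p,
       note = NULL)
}

#' Pairwise and triple overlaps of protein sets
#'
#' Intersection counts for up to three id sets (e.g. proteins associated
#' with ePVS, WMH and BPF), with per-id effect-direction concordance flags
#' when directions are supplied.
#'
#' @param setA,setB,setC Character id sets (`setC` optional).
#' @param directions Optional list of named direction vectors
#'   (`"positive"`/`"negative"`), one per set, names = ids.
#' @return List: `ab`, `ac`, `bc`, `abc` counts, `ids` (per-intersection id
#'   vectors), and `concordant` (per-pair logical vectors) when directions
#'   are given.
#' @export
overlap_sets <- function(setA, setB, setC = NULL, directions = NULL) {
  setA <- unique(setA); setB <- unique(setB)
  setC <- if (is.null(setC)) character(0) else unique(setC)
  ab <- intersect(setA, setB); ac <- intersect(setA, setC)
  bc <- intersect(setB, setC); abc <- intersect(ab, setC)
  out <- list(ab = length(ab), ac = length(ac), bc = length(bc),
              abc = length(abc),
              ids = list(ab = ab, ac = ac, bc = bc, abc = abc))
  if (!is.null(directions)) {
    conc <- function(ids, d1, d2) {
      if (!length(ids)) return(stats::setNames(logical(0), character(0)))
      stats::setNames(d1[ids] == d2[ids], ids)
    }
    out$concordant <- list(
      ab = conc(ab, directions[[1]], directions[[2]]),
      ac = conc(ac, directions[[1]], directions[[3]]),
      bc = conc(bc, directions[[2]], directions[[3]])
    )
  }
  out
}
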