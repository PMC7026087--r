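#' Signed ranked gene list for RRHO
#'
#' Genes are scored by `-log10(p) * direction` (p floored at 1e-300;
#' zero-effect genes score 0) and sorted in decreasing score order, so the
#' top of the list holds the most significantly upregulated genes and the
#' bottom the most significantly downregulated.  Ties are broken by gene
#' id for reproducibility.
#'
#' @param result A [de_test()] result (needs `p_value` and `direction`).
#' @return data.frame of class `ranked_list` with columns `gene`, `score`,
#'   in rank order.
#' @export
make_ranked_list <- function(result) {
  if (is.null(result$p_value) || is.null(result$direction) ||
      any(is.na(result$p_value)) || any(is.na(result$direction))) {
    stop("result must provide complete p_value and direction columns")
  }
  score <- -log10(pmax(result$p_value, 1e-300)) * result$direction
  ord <- order(-score, result$gene)
  out <- data.frame(gene = result$gene[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# overlap counts k[i,j] = #genes with rank_a <= ti and rank_b <= tj, for
# rank permutations ra/rb aligned to the same gene order
overlap_counts <- function(ra, rb, ti, tj) {
  rb_by_a <- rb[order(ra)]           # position i holds the gene with ra = i
  k <- matrix(0L, length(ti), length(tj))
  for (j in seq_along(tj)) {
    cs <- cumsum(rb_by_a <= tj[j])
    k[, j] <- cs[ti]
  }
  k
}

# signed -log10 exact hypergeometric tails: positive = over-enrichment
# (k at or above expectation), negative = under-enrichment
signed_overlap_grid <- function(k, ti, tj, n) {
  tim <- matrix(ti, length(ti), length(tj))
  tjm <- matrix(tj, length(ti), length(tj), byrow = TRUE)
  expected <- tim * tjm / n
  log_over <- phyper(k - 1, tim, n - tim, tjm, lower.tail = FALSE,
                     log.p = TRUE)
  log_under <- phyper(k, tim, n - tim, tjm, lower.tail = TRUE, log.p = TRUE)
  ifelse(k >= expected, -log_over / log(10), log_under / log(10))
}

#' Rank-rank hypergeometric overlap map
#'
#' For every pair of rank thresholds (multiples of `step`) the overlap
#' `k = |top_i(A) ∩ top_j(B)|` between the two list heads is scored
#' against the hypergeometric null: the cell holds `-log10 P(X >= k)`
#' when k meets or exceeds its expectation `i*j/N` (over-enrichment,
#' positive values) and `log10 P(X <= k)` otherwise (under-enrichment,
#' negative values).  Tail probabilities are exact, computed in log
#' space.
#'
#' @param list_a,list_b [make_ranked_list()] objects over the same gene
#'   universe.
#' @param step Rank stride; default `max(1, floor(N/100))` giving a grid
#'   of about 100 x 100.
#' @return Object of class `rrho_map`: `grid` (rows = thresholds in
#'   `list_a`, cols = `list_b`), `k`, `thresholds`, `step`, `n_genes`,
#'   `midpoint_a`/`midpoint_b` (rank where each list's score changes
#'   sign), and the two ranked lists.
#' @export
rrho_map <- function(list_a, list_b, step = NULL) {
  stopifnot(inherits(list_a, "ranked_list"), inherits(list_b, "ranked_list"))
  if (nrow(list_a) != nrow(list_b) || !setequal(list_a$gene, list_b$gene)) {
    nd <- length(setdiff(list_a$gene, list_b$gene)) +
          length(setdiff(list_b$gene, list_a$gene))
    stop("gene universes differ (symmetric difference of size ", nd, ")")
  }
  n <- nrow(list_a)
  if (is.null(step)) step <- max(1L, floor(n / 100))
  step <- as.integer(step)
  if (step < 1L || n < 2L * step) stop("need N >= 2*step")
  thresholds <- pmin(seq_len(ceiling(n / step)) * step, n)

  ra <- seq_len(n)
  rb <- match(list_a$gene, list_b$gene)   # rank in B of A's i-th gene
  k <- overlap_counts(ra, rb, thresholds, thresholds)
  grid <- signed_overlap_grid(k, thresholds, thresholds, n)

  structure(list(grid = grid, k = k, thresholds = thresholds, step = step,
                 n_genes = n,
                 midpoint_a = sum(list_a$score > 0),
                 midpoint_b = sum(list_b$score > 0),
                 list_a = list_a, list_b = list_b,
                 corrected = NULL, correction = NULL),
            class = "rrho_map")
}

#' Multiple-testing correction of an RRHO grid
#'
#' Either Benjamini-Yekutieli over all grid cells (valid under arbitrary
#' dependence) or a max-statistic permutation null obtained by
#' re-randomizing one gene list.
#'
#' @param map An [rrho_map()] object.
#' @param method `"BY"` or `"permutation"`.
#' @param n_perm Number of permutations (>= 20) for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return The map with `corrected` (signed -log10 corrected p grid) and
#'   `correction` filled in.
#' @export
correct_map <- function(map, method = c("BY", "permutation"),
                        n_perm = 200, seed = 1L) {
  method <- match.arg(method)
  p <- 10^(-abs(map$grid))
  if (method == "BY") {
    adj <- matrix(p.adjust(p, "BY"), nrow(p), ncol(p))
  } else {
    if (n_perm < 20) stop("permutation correction needs at least 20 permutations")
    set.seed(seed)
    obs <- abs(map$grid)
    exceed <- matrix(0, nrow(obs), ncol(obs))
    lb <- map$list_b
    for (s in seq_len(n_perm)) {
      perm <- lb
      perm$gene <- lb$gene[sample.int(nrow(lb))]
      null_max <- max(abs(rrho_map(map$list_a, perm, step = map$step)$grid))
      exceed <- exceed + (null_max >= obs)
    }
    adj <- (1 + exceed) / (n_perm + 1)
  }
  map$corrected <- sign(map$grid) * -log10(pmax(adj, 1e-300))
  map$correction <- method
  map
}

#' Classify RRHO quadrants into a coherence call
#'
#' Stratified (two-sided) quadrant semantics: each quadrant is scored
#' from the appropriate ends of the two lists, restricted to ranks up to
#' each list's sign-change midpoint — up-up overlaps the two heads,
#' down-down the two tails, up-down the head of list A with the tail of
#' list B, down-up the reverse.  The call is `coherent` if significant
#' over-enrichment occurs only in concordant quadrants (up-up /
#' down-down), `anti-coherent` if only in discordant quadrants, `mixed`
#' if in both, `none` otherwise.
#'
#' @param map An [rrho_map()] object.
#' @param signif Significance threshold on the -log10 scale; default is
#'   Bonferroni at the number of quadrant cells evaluated.
#' @return List of class `quadrant_summary`: per-quadrant maxima with
#'   their rank-threshold locations, the threshold used, and the overall
#'   `call`.
#' @export
classify_quadrants <- function(map, signif = NULL) {
  n <- map$n_genes
  step <- map$step
  mid_a <- map$midpoint_a
  mid_b <- map$midpoint_b
  ra_head <- seq_len(n)                                # rank from the top
  rb_head <- match(map$list_a$gene, map$list_b$gene)
  ra_tail <- n + 1L - ra_head                          # rank from the bottom
  rb_tail <- n + 1L - rb_head

  thr <- function(m) if (m >= 1L) pmin(seq_len(ceiling(m / step)) * step, m)
                     else integer(0)
  quadrant <- function(ra, rb, ia, jb) {
    ti <- thr(ia); tj <- thr(jb)
    if (length(ti) == 0L || length(tj) == 0L) return(NULL)
    k <- overlap_counts(ra, rb, ti, tj)
    g <- signed_overlap_grid(k, ti, tj, n)
    w <- which(g == max(g), arr.ind = TRUE)[1, ]
    list(max_cell = max(g), rank_a = ti[w[1]], rank_b = tj[w[2]],
         n_cells = length(g))
  }
  qs <- list(
    "up-up" = quadrant(ra_head, rb_head, mid_a, mid_b),
    "down-down" = quadrant(ra_tail, rb_tail, n - mid_a, n - mid_b),
    "up-down" = quadrant(ra_head, rb_tail, mid_a, n - mid_b),
    "down-up" = quadrant(ra_tail, rb_head, n - mid_a, mid_b))
  n_cells <- sum(vapply(qs, function(q) if (is.null(q)) 0L else q$n_cells,
                        integer(1)))
  if (is.null(signif)) signif <- -log10(0.05 / max(n_cells, 1L))
  tab <- do.call(rbind, lapply(names(qs), function(nm) {
    q <- qs[[nm]]
    data.frame(quadrant = nm,
               max_cell = if (is.null(q)) NA_real_ else q$max_cell,
               rank_a = if (is.null(q)) NA_integer_ else q$rank_a,
               rank_b = if (is.null(q)) NA_integer_ else q$rank_b,
               stringsAsFactors = FALSE)
  }))
  tab$significant <- !is.na(tab$max_cell) & tab$max_cell >= signif
  sig_kind <- ifelse(tab$quadrant %in% c("up-up", "down-down"),
                     "concordant", "discordant")[tab$significant]
  call <- if (length(sig_kind) == 0L) "none"
          else if (all(sig_kind == "concordant")) "coherent"
          else if (all(sig_kind == "discordant")) "anti-coherent"
          else "mixed"
  structure(list(quadrants = tab, call = call, signif = signif),
            class = "quadrant_summary")
}
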