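#' Define a two-group contrast over the sample design
#'
#' Groups are given as named lists of design-column filters (a sample
#' matches if every named column value is in the given set), evaluated
#' within an optional fixed stratum.  For example the overall-sex contrast
#' in the non-stressed BLA is
#' `make_contrast("sex", list(genotype = "XX_F"), list(genotype = "XY_M"),
#' list(stress = "ctrl", region = "BLA"))`.
#'
#' @param name Contrast label.
#' @param group_a,group_b Named lists of design filters.
#' @param stratum Named list of design filters applied to both groups.
#' @return An object of class `contrast`.
#' @export
make_contrast <- function(name, group_a, group_b, stratum = list()) {
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 stratum = stratum), class = "contrast")
}

match_predicate <- function(design, pred) {
  keep <- rep(TRUE, nrow(design))
  for (col in names(pred)) {
    if (!col %in% names(design)) stop("unknown design column: ", col)
    keep <- keep & design[[col]] %in% pred[[col]]
  }
  keep
}

#' Resolve a contrast to the two sample-id groups
#'
#' @param design Sample design data.frame.
#' @param contrast A [make_contrast()] object.
#' @return List with character vectors `a` and `b` of sample ids.
#' @export
contrast_samples <- function(design, contrast) {
  in_stratum <- match_predicate(design, contrast$stratum)
  a <- design$sample_id[in_stratum & match_predicate(design, contrast$group_a)]
  b <- design$sample_id[in_stratum & match_predicate(design, contrast$group_b)]
  if (length(intersect(a, b)) > 0L) {
    stop("contrast groups overlap within the stratum")
  }
  if (length(a) == 0L || length(b) == 0L) {
    stop("contrast '", contrast$name, "' has an empty group")
  }
  list(a = a, b = b)
}

# inverse of trigamma by Newton iteration (monotone decreasing function)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# method-of-moments empirical-Bayes fit of the variance prior on log s^2
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e_adj <- z - digamma(df / 2) + log(df / 2)
  ev <- var(z) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(mean(e_adj))))
  }
  df_prior <- 2 * trigamma_inverse(ev)
  s2_prior <- exp(mean(e_adj) + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

row_group_stats <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}

#' Per-gene two-group differential expression test
#'
#' Default is a two-sample Welch t test on log2 expression.  With
#' `moderated = TRUE`, gene-wise pooled variances are shrunk toward a
#' common prior estimated by the method of moments on the distribution of
#' log sample variances (empirical Bayes), and the t statistic uses the
#' posterior variance with augmented degrees of freedom.
#'
#' @param expr log2 expression matrix (genes x samples, sample ids as
#'   colnames).
#' @param design Sample design data.frame.
#' @param contrast A [make_contrast()] object; effects are reported as
#'   group A minus group B on the log2 scale.
#' @param moderated Use the empirical-Bayes moderated t instead of Welch.
#' @return data.frame (class `de_result`) with per-gene `gene`, `log2fc`,
#'   `fold_change` (= `2^|log2fc|`, always >= 1), `t_stat`, `df`,
#'   `p_value`, `q_value` (Benjamini-Hochberg over all tested genes) and
#'   `direction` (sign of `log2fc`).
#' @export
de_test <- function(expr, design, contrast, moderated = FALSE) {
  if (inherits(expr, "weighted_expr")) expr <- expr$E
  stopifnot(is.matrix(expr))
  grp <- contrast_samples(design, contrast)
  if (length(grp$a) < 2L || length(grp$b) < 2L) {
    stop("each contrast group needs at least 2 samples")
  }
  xa <- expr[, grp$a, drop = FALSE]
  xb <- expr[, grp$b, drop = FALSE]
  sa <- row_group_stats(xa)
  sb <- row_group_stats(xb)
  log2fc <- sa$mean - sb$mean
  if (moderated) {
    df0 <- sa$n + sb$n - 2
    s2 <- ((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / df0
    prior <- fit_variance_prior(s2, df0)
    if (is.finite(prior$df_prior)) {
      s2_post <- (prior$df_prior * prior$s2_prior + df0 * s2) /
                 (prior$df_prior + df0)
      df_total <- df0 + prior$df_prior
    } else {
      s2_post <- rep(prior$s2_prior, length(s2))
      df_total <- Inf
    }
    se <- sqrt(s2_post * (1 / sa$n + 1 / sb$n))
    tt <- log2fc / se
    df <- rep(df_total, length(tt))
  } else {
    va <- sa$var / sa$n
    vb <- sb$var / sb$n
    se <- sqrt(va + vb)
    tt <- log2fc / se
    df <- (va + vb)^2 /
          (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(tt)] <- 1            # zero-variance, zero-difference genes
  tt[!is.finite(tt)] <- 0
  res <- data.frame(gene = rownames(expr), log2fc = log2fc,
                    fold_change = 2^abs(log2fc), t_stat = tt, df = df,
                    p_value = p, q_value = p.adjust(p, "BH"),
                    direction = sign(log2fc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- contrast$name
  class(res) <- c("de_result", "data.frame")
  res
}

#' Apply the differential-expression rule
#'
#' A gene is called DE iff `p_value < p_max` and `fold_change > fc_min`
#' (both strict), using raw p values; the study's rule is p < 0.05 and
#' linear fold change > 1.3.
#'
#' @param result A [de_test()] result.
#' @param p_max,fc_min Thresholds (must be positive).
#' @return data.frame with the called genes: `gene`, `log2fc`, `direction`.
#' @export
call_de <- function(result, p_max = 0.05, fc_min = 1.3) {
  stopifnot(p_max > 0, fc_min > 0)
  keep <- result$p_value < p_max & result$fold_change > fc_min
  out <- result[keep, c("gene", "log2fc", "direction")]
  rownames(out) <- NULL
  out
}

as_de_set <- function(x) {
  if (is.data.frame(x)) {
    data.frame(gene = as.character(x$gene),
               direction = if ("direction" %in% names(x)) x$direction
                           else rep(NA_real_, nrow(x)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = as.character(x), direction = NA_real_,
               stringsAsFactors = FALSE)
  }
}

#' Attribute overall sex differences to gonadal and/or genetic sex
#'
#' Intersects the overall sex-difference DE set (XX Female vs XY Male)
#' with the gonadal-sex DE set (gonadal F vs M) and the genetic-sex DE set
#' (XX vs XY).  With `require_direction_match = TRUE` (default) a gene
#' counts as "driven by" a factor only when the direction agrees, with the
#' convention that all three contrasts are oriented female/XX-high
#' positive.  All seven Venn regions of the three sets are reported, plus
#' the percentage of sex-DE genes attributed to each factor.
#'
#' @param sex_de,gonadal_de,genetic_de DE sets: data.frames with `gene`
#'   and `direction` columns (e.g. from [call_de()]) or plain character
#'   vectors (direction then ignored).
#' @param require_direction_match Require the sign of the effect to agree.
#' @return A list of class `venn_partition`: `venn` (counts of the 7
#'   regions), `n_sex`, `pct_gonadal`, `pct_genetic`, and the attributed
#'   gene sets `driven_gonadal`, `driven_genetic`, `driven_both`.
#' @export
attribute_sex_differences <- function(sex_de, gonadal_de, genetic_de,
                                      require_direction_match = TRUE) {
  s <- as_de_set(sex_de); g <- as_de_set(gonadal_de); x <- as_de_set(genetic_de)
  match_dir <- function(a, b) {
    shared <- intersect(a$gene, b$gene)
    if (!require_direction_match || length(shared) == 0L) return(shared)
    da <- a$direction[match(shared, a$gene)]
    db <- b$direction[match(shared, b$gene)]
    ok <- is.na(da) | is.na(db) | da == db
    shared[ok]
  }
  sg <- match_dir(s, g)
  sx <- match_dir(s, x)
  S <- s$gene; G <- g$gene; X <- x$gene
  venn <- c(
    sex_only = length(setdiff(S, union(G, X))),
    gonadal_only = length(setdiff(G, union(S, X))),
    genetic_only = length(setdiff(X, union(S, G))),
    sex_gonadal = length(setdiff(intersect(S, G), X)),
    sex_genetic = length(setdiff(intersect(S, X), G)),
    gonadal_genetic = length(setdiff(intersect(G, X), S)),
    all_three = length(intersect(S, intersect(G, X))))
  n_sex <- length(S)
  structure(list(
    venn = venn, n_sex = n_sex,
    pct_gonadal = if (n_sex) 100 * length(sg) / n_sex else 0,
    pct_genetic = if (n_sex) 100 * length(sx) / n_sex else 0,
    driven_gonadal = sg, driven_genetic = sx,
    driven_both = intersect(sg, sx)), class = "venn_partition")
}

#' Overlap statistics between two DE gene sets
#'
#' @param a,b Character vectors of gene ids (or data.frames with a `gene`
#'   column).
#' @return List with `n_a`, `n_b`, `n_intersect`, `jaccard`, `pct_of_a`,
#'   `pct_of_b`.
#' @export
stress_overlap <- function(a, b) {
  if (is.data.frame(a)) a <- a$gene
  if (is.data.frame(b)) b <- b$gene
  a <- unique(as.character(a)); b <- unique(as.character(b))
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = i,
       jaccard = if (u) i / u else NA_real_,
       pct_of_a = if (length(a)) 100 * i / length(a) else NA_real_,
       pct_of_b = if (length(b)) 100 * i / length(b) else NA_real_)
}
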