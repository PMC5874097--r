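## Cohort statistics: Pearson correlation of pharmacokinetic parameters
## with microvessel density, Wilcoxon signed-rank contrasts between
## subregions (exact distribution with midranks up to n = 25), and the
## combined PNA+VTA analysis. Two-sided p-values throughout; no
## multiple-testing correction (each test is reported at its nominal
## level).

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation with the usual two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   positive variance
#' @return list with \code{r}, \code{p}, \code{n}
#' @examples
#' pearsonCorrelation(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

## exact null distribution of the positive-rank sum with midranks:
## generating polynomial over doubled ranks (so midranks stay integral)
signedRankExactP <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)   # f[s + 1] = #sign vectors with doubled sum s
  f[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
    f <- f + shifted
  }
  probs <- f / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  lower <- sum(probs[seq_len(v2 + 1)])
  upper <- sum(probs[(v2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired signed-rank test with the classical zero-handling: pairs with
#' zero difference are dropped, tied absolute differences receive
#' midranks. For 25 or fewer informative pairs the p-value comes from the
#' exact permutation distribution of the positive-rank sum (computed by
#' convolution over the doubled midranks, so ties are handled exactly);
#' above that, the normal approximation with tie correction and continuity
#' correction is used. All differences zero is a degenerate input and is
#' flagged rather than tested.
#'
#' @param a,b paired numeric vectors
#' @return list with \code{statistic} (positive-rank sum V), \code{p},
#'   \code{nPairs} (informative pairs), \code{degenerate}
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 1, 2, 2))$p
#' @export
wilcoxonSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, nPairs = 0L,
                degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    p <- signedRankExactP(r, v)
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, p = p, nPairs = n, degenerate = FALSE)
}

#' Combine PNA and VTA rows per tumor
#'
#' The combined analysis averages each tumor's PNA and VTA values
#' (unweighted, for each parameter and for the microvessel count), keeping
#' one record per tumor. A \code{"pooled"} mode concatenating the PNA and
#' VTA rows (doubling n) is available for sensitivity analysis. Tumors
#' missing either region are excluded with a warning.
#'
#' @param records summary table with columns \code{tumor_id},
#'   \code{region}, \code{ktrans}, \code{ve}, \code{vp}, \code{mvd}
#' @param mode \code{"mean"} (default) or \code{"pooled"}
#' @return data.frame in the same schema, region \code{"PNA+VTA"}
#' @export
combinePnaVta <- function(records, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  keep <- records[records$region %in% c("PNA", "VTA"), , drop = FALSE]
  if (mode == "pooled") {
    out <- keep[, c("tumor_id", "region", "ktrans", "ve", "vp", "mvd")]
    out$region <- "PNA+VTA"
    rownames(out) <- NULL
    return(out)
  }
  ids <- unique(keep$tumor_id)
  rows <- lapply(ids, function(tid) {
    sub <- keep[keep$tumor_id == tid, , drop = FALSE]
    if (!all(c("PNA", "VTA") %in% sub$region)) {
      warning(sprintf("tumor %s lacks a PNA or VTA row; excluded", tid))
      return(NULL)
    }
    p <- sub[sub$region == "PNA", ][1, ]
    v <- sub[sub$region == "VTA", ][1, ]
    data.frame(tumor_id = tid, region = "PNA+VTA",
               ktrans = (p$ktrans + v$ktrans) / 2,
               ve = (p$ve + v$ve) / 2, vp = (p$vp + v$vp) / 2,
               mvd = (p$mvd + v$mvd) / 2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full correlation and subregion-contrast analysis
#'
#' Runs the whole statistical battery on a cohort summary table:
#' Pearson correlations of Ktrans, ve and vp against microvessel density
#' within CNA, PNA, VTA and the combined PNA+VTA means, and Wilcoxon
#' signed-rank contrasts of each parameter (and of the microvessel count)
#' between every subregion pair.
#'
#' @param records summary table (one row per tumor and region) with
#'   columns \code{tumor_id}, \code{region}, \code{ktrans}, \code{ve},
#'   \code{vp}, \code{mvd}
#' @param combineMode how PNA+VTA are combined, see
#'   \code{\link{combinePnaVta}}
#' @return list with data.frames \code{correlations} (region_set,
#'   parameter, r, p, n) and \code{paired} (region_pair, quantity,
#'   statistic, p, n_pairs), and a character vector \code{report}
#' @examples
#' res <- runFullAnalysis(loadTable1Fixture())
#' subset(res$correlations, parameter == "ktrans")
#' @export
runFullAnalysis <- function(records, combineMode = "mean") {
  params <- c("ktrans", "ve", "vp")
  regions <- c("CNA", "PNA", "VTA")
  tabs <- lapply(regions, function(rg) {
    sub <- records[records$region == rg, , drop = FALSE]
    sub[order(sub$tumor_id), , drop = FALSE]
  })
  names(tabs) <- regions
  tabs[["PNA+VTA"]] <- combinePnaVta(records, combineMode)
  cors <- do.call(rbind, lapply(names(tabs), function(rg) {
    sub <- tabs[[rg]]
    do.call(rbind, lapply(params, function(pp) {
      pc <- pearsonCorrelation(sub[[pp]], sub$mvd)
      data.frame(region_set = rg, parameter = pp, r = pc$r, p = pc$p,
                 n = pc$n)
    }))
  }))
  pairs <- list(c("CNA", "PNA"), c("CNA", "VTA"), c("PNA", "VTA"))
  paired <- do.call(rbind, lapply(pairs, function(pr) {
    a <- tabs[[pr[1]]]; b <- tabs[[pr[2]]]
    common <- intersect(a$tumor_id, b$tumor_id)
    a <- a[match(common, a$tumor_id), ]
    b <- b[match(common, b$tumor_id), ]
    do.call(rbind, lapply(c(params, "mvd"), function(q) {
      w <- wilcoxonSignedRank(a[[q]], b[[q]])
      data.frame(region_pair = paste(pr, collapse = "-"), quantity = q,
                 statistic = w$statistic, p = w$p, n_pairs = w$nPairs)
    }))
  }))
  rownames(cors) <- rownames(paired) <- NULL
  fmtp <- function(p) ifelse(p < 1e-4, sprintf("%.2e", p),
                             sprintf("%.4f", p))
  rep1 <- vapply(seq_len(nrow(cors)), function(i) sprintf(
    "%s: %s vs MVD r = %.4f, p = %s (n = %d)", cors$region_set[i],
    cors$parameter[i], cors$r[i], fmtp(cors$p[i]), cors$n[i]),
    character(1))
  rep2 <- vapply(seq_len(nrow(paired)), function(i) sprintf(
    "%s: %s V = %.1f, p = %s (n = %d)", paired$region_pair[i],
    paired$quantity[i], paired$statistic[i], fmtp(paired$p[i]),
    paired$n_pairs[i]), character(1))
  list(correlations = cors, paired = paired,
       report = c("Correlations with MVD:", rep1, "",
                  "Subregion contrasts (Wilcoxon signed-rank):", rep2))
}
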