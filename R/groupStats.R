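#' One-sample t-test summary
#'
#' Two-sided test of mean zero; t = mean / (sd / sqrt(n)) with the n-1
#' denominator in sd and n-1 degrees of freedom.
#'
#' @param values numeric vector, length >= 2.
#' @return List: mean, sd, n, t, p, df, degenerate (TRUE when the sample
#'   variance is zero, in which case t and p are NA).
#' @export
oneSampleT <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values); s <- sd(values); n <- length(values)
  if (s == 0)
    return(list(mean = m, sd = s, n = n, t = NA_real_, p = NA_real_,
                df = n - 1L, degenerate = TRUE))
  ht <- t.test(values, mu = 0)
  list(mean = m, sd = s, n = n, t = unname(ht$statistic),
       p = ht$p.value, df = n - 1L, degenerate = FALSE)
}

#' Pooled-variance independent-samples t-test
#'
#' t = (mean_A - mean_B) / (s_p sqrt(1/n1 + 1/n2)) with pooled variance
#' s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2), two-sided p on n1+n2-2
#' degrees of freedom. \code{direction} controls which group plays A.
#'
#' @param g1,g2 numeric vectors (n >= 2 each).
#' @param direction "g1-g2" (default) or "g2-g1".
#' @return List: t, p, df, direction, degenerate (both groups zero variance).
#' @export
twoSampleTPooled <- function(g1, g2, direction = c("g1-g2", "g2-g1")) {
  direction <- match.arg(direction)
  stopifnot(length(g1) >= 2L, length(g2) >= 2L)
  if (sd(g1) == 0 && sd(g2) == 0)
    return(list(t = NA_real_, p = NA_real_,
                df = length(g1) + length(g2) - 2L, direction = direction,
                degenerate = TRUE))
  a <- if (direction == "g1-g2") g1 else g2
  b <- if (direction == "g1-g2") g2 else g1
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = length(g1) + length(g2) - 2L, direction = direction,
       degenerate = FALSE)
}

#' Pooled-variance t from group summaries
#'
#' Recomputes the independent-samples pooled t-score from printed group
#' summaries (means, SDs, sizes); the difference is taken first minus second.
#'
#' @param mean1,sd1,n1 first group's summary.
#' @param mean2,sd2,n2 second group's summary.
#' @return List: t, p, df.
#' @export
twoSampleTPooledSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

.paramClass <- function(name) {
  prefix <- sub(":.*$", "", name)
  c(A = "intrinsic", Blow = "modulation-low", Bhigh = "modulation-high",
    C = "driving")[prefix]
}

#' Group statistics table for averaged connectivity parameters
#'
#' For every intrinsic and modulation parameter: group means, SDs and
#' one-sample t-tests per group, and the pooled independent-samples t-test
#' between groups. The inter-group difference is signed HC - OCD for intrinsic
#' parameters and OCD - HC for modulation parameters (the reporting conventions
#' of the two summary tables differ). No multiple-comparison correction is
#' applied to the significance flags; a Benjamini-Hochberg column is emitted
#' additionally.
#'
#' @param hc,ocd subjects x parameters matrices of subject-level BMA estimates
#'   (or \linkS4class{BmaResult} objects) with identical column names.
#' @param alpha significance level for the flags (default 0.05).
#' @param includeDriving also emit rows for driving-input parameters
#'   (default FALSE: the reported tables cover couplings only).
#' @return data.frame, one row per parameter: class, pathway, hc_mean, hc_sd,
#'   hc_t, hc_p, hc_sig, ocd_* likewise, inter_direction, inter_t, inter_p,
#'   inter_p_bh, inter_sig, degenerate.
#' @export
buildStatsTable <- function(hc, ocd, alpha = 0.05, includeDriving = FALSE) {
  hm <- if (is(hc, "BmaResult")) hc@estimates else as.matrix(hc)
  om <- if (is(ocd, "BmaResult")) ocd@estimates else as.matrix(ocd)
  if (!identical(colnames(hm), colnames(om)))
    stop("HC and OCD parameter names do not match")
  params <- colnames(hm)
  cls <- .paramClass(params)
  if (!includeDriving) {
    keep <- cls != "driving"
    params <- params[keep]; cls <- cls[keep]
  }
  rows <- lapply(seq_along(params), function(i) {
    pn <- params[i]
    h1 <- oneSampleT(hm[, pn])
    o1 <- oneSampleT(om[, pn])
    dir <- if (cls[i] == "intrinsic") "HC-OCD" else "OCD-HC"
    t2 <- if (dir == "HC-OCD") twoSampleTPooled(hm[, pn], om[, pn], "g1-g2")
          else twoSampleTPooled(om[, pn], hm[, pn], "g1-g2")
    data.frame(class = cls[i], pathway = sub("^[^:]+:", "", pn),
               parameter = pn,
               hc_mean = h1$mean, hc_sd = h1$sd, hc_t = h1$t, hc_p = h1$p,
               ocd_mean = o1$mean, ocd_sd = o1$sd, ocd_t = o1$t, ocd_p = o1$p,
               inter_direction = dir, inter_t = t2$t, inter_p = t2$p,
               degenerate = h1$degenerate || o1$degenerate || t2$degenerate,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$inter_p_bh <- p.adjust(tab$inter_p, method = "BH")
  tab$hc_sig <- !is.na(tab$hc_p) & tab$hc_p < alpha
  tab$ocd_sig <- !is.na(tab$ocd_p) & tab$ocd_p < alpha
  tab$inter_sig <- !is.na(tab$inter_p) & tab$inter_p < alpha
  rownames(tab) <- NULL
  tab
}

#' Write a stats table as TSV
#' @param tab data.frame from \code{\link{buildStatsTable}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStatsTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
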