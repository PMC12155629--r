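#' Jaro-Winkler string similarity
#'
#' Standard Jaro similarity with the Winkler common-prefix boost, used as the
#' string-distance kernel of the drug-name harmonization stage. Characters of
#' `s1` and `s2` match when equal (after case folding) and no further apart
#' than `floor(max(|s1|, |s2|) / 2) - 1` positions; with `m` matches and `t`
#' half-transpositions the Jaro score is
#' `J = (m/|s1| + m/|s2| + (m - t)/m) / 3`, and the returned value is
#' `J + l * 0.1 * (1 - J)` where `l` is the length of the common prefix,
#' capped at 4.
#'
#' @param s1,s2 Character vectors, recycled to a common length. Comparison is
#'   case-insensitive; two empty strings score 1 by convention.
#' @return Numeric vector of similarities in `[0, 1]`. The score is symmetric
#'   in its arguments and equals 1 exactly when the case-folded strings are
#'   equal.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")   # 0.9611
#' jaro_winkler("FUROSEMID", "FUROSEMIDD")
#' @export
jaro_winkler <- function(s1, s2) {
  if (length(s1) == 0L || length(s2) == 0L) return(numeric(0))
  n <- max(length(s1), length(s2))
  s1 <- rep_len(toupper(as.character(s1)), n)
  s2 <- rep_len(toupper(as.character(s2)), n)
  vapply(seq_len(n), function(i) .jw_one(s1[[i]], s2[[i]]), numeric(1))
}

.jw_one <- function(s1, s2) {
  if (is.na(s1) || is.na(s2)) return(NA_real_)
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  la <- length(a)
  lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)

  window <- max(floor(max(la, lb) / 2) - 1, 0L)
  a_match <- logical(la)
  b_match <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!b_match[j] && a[i] == b[j]) {
        a_match[i] <- TRUE
        b_match[j] <- TRUE
        break
      }
    }
  }
  m <- sum(a_match)
  if (m == 0L) return(0)

  # transpositions: matched characters out of order, counted in halves
  t <- sum(a[a_match] != b[b_match]) / 2
  jaro <- (m / la + m / lb + (m - t) / m) / 3

  l <- 0L
  for (k in seq_len(min(4L, la, lb))) {
    if (a[k] == b[k]) l <- l + 1L else break
  }
  jaro + l * 0.1 * (1 - jaro)
}
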