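# Relative quantification of PCR-tagged cell mixes from qPCR Ct values
# (2^dCt against a time-zero reference mix) and exact Wilcoxon signed-rank
# testing of proportion shifts.

#' Tag proportions from Ct values (2^dCt)
#'
#' Relative quantity of each tag is `2^(Ct_reference - Ct_tumor)` — more
#' abundant tags amplify earlier (lower Ct) and get larger quantities —
#' renormalized to sum to one within each tumor. Adding a constant to all
#' of one tumor's Ct values (total-input differences) therefore cancels
#' exactly. Not-detected tags contribute quantity zero and keep their flag.
#'
#' @param experiment List with `ct` (data.frame `tumor_id`, `tag`, `ct`,
#'   optional `site`, optional logical `detected`) and `reference`
#'   (data.frame `tag`, `ct`), as produced by [generate_tag_experiment()]
#'   or read from CSV.
#' @return Data.frame (`TagProportion`): `tumor_id`, `site`, `tag`,
#'   `quantity`, `proportion`, `detected`.
#' @export
tag_proportions <- function(experiment) {
  ct <- experiment$ct
  ref <- experiment$reference
  stopifnot(all(c("tumor_id", "tag", "ct") %in% names(ct)),
            all(c("tag", "ct") %in% names(ref)))
  if (!"detected" %in% names(ct)) ct$detected <- !is.na(ct$ct)
  if (!"site" %in% names(ct)) ct$site <- NA_character_
  missing_ref <- setdiff(unique(ct$tag), ref$tag)
  if (length(missing_ref))
    stop("no reference Ct for tag(s): ", paste(missing_ref, collapse = ", "))
  tags_per_tumor <- table(ct$tumor_id)
  if (any(tags_per_tumor < 2)) stop("every tumor needs >= 2 tags")
  ref_ct <- ref$ct[match(ct$tag, ref$tag)]
  quantity <- ifelse(ct$detected, 2^(ref_ct - ct$ct), 0)
  totals <- tapply(quantity, ct$tumor_id, sum)
  if (any(totals <= 0)) stop("tumor with no detected tags: ",
                             paste(names(totals)[totals <= 0], collapse = ", "))
  out <- data.frame(tumor_id = ct$tumor_id, site = ct$site, tag = ct$tag,
                    quantity = quantity,
                    proportion = quantity / as.numeric(totals[ct$tumor_id]),
                    detected = ct$detected, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test of tag proportions against a null value
#'
#' Exact two-sided signed-rank test of H0: the distribution of proportions
#' is symmetric about `null` (default 0.5, an equal mix). Zeros (values
#' exactly at the null) are dropped, ties take midranks, and the exact null
#' distribution of the rank sum is enumerated by convolution for n <= 25
#' (equivalent to enumerating all 2^n sign patterns, tied midranks
#' included); above that a normal approximation with tie correction is
#' used.
#'
#' @param proportions Numeric vector of per-tumor proportions for one tag.
#' @param null Null center (default 0.5).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (greater: proportions exceed the null).
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return List with `p`, `statistic` (positive-rank sum W+), `n_used`,
#'   `method`.
#' @export
signed_rank_test <- function(proportions, null = 0.5,
                             alternative = c("two.sided", "greater", "less"),
                             exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- proportions[!is.na(proportions)] - null
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(p = 1, statistic = NA_real_, n_used = 0L,
                      method = "degenerate (all at null)"))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- round(2 * r)
    total <- sum(ranks2)
    dist <- numeric(total + 1)
    dist[1] <- 1
    for (rr in ranks2)
      dist <- dist + c(rep(0, rr), dist[seq_len(total + 1 - rr)])
    dist <- dist / sum(dist)
    w2 <- round(2 * w_plus)
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):(total + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact (sign-pattern enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(p = p, statistic = w_plus, n_used = n, method = method)
}

#' Compare two tags' proportions across tumors
#'
#' Convenience wrapper: extracts one tag's per-tumor proportions from a
#' [tag_proportions()] table (optionally restricted to one site) and tests
#' them against an equal-mix null with [signed_rank_test()].
#'
#' @param proportions Output of [tag_proportions()].
#' @param tag Tag whose proportion is tested.
#' @param site Optional site restriction (`"primary"` / `"metastasis"`).
#' @param null,alternative Passed to [signed_rank_test()].
#' @return The [signed_rank_test()] result with `n_tumors` added.
#' @export
test_tag_shift <- function(proportions, tag, site = NULL, null = 0.5,
                           alternative = "two.sided") {
  d <- proportions[proportions$tag == tag, , drop = FALSE]
  if (!is.null(site)) d <- d[!is.na(d$site) & d$site == site, , drop = FALSE]
  if (nrow(d) < 5) warning("fewer than 5 tumors; the signed-rank test has little power")
  out <- signed_rank_test(d$proportion, null = null, alternative = alternative)
  out$n_tumors <- nrow(d)
  out
}
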