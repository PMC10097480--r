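# Evaluation layer: majority vote over blinded observers, Fleiss kappa,
# empirical ROC/AUC of the detector score against the majority label, and
# sensitivity/specificity at chosen cutoffs.

check_ratings <- function(ratings) {
    m <- as.matrix(ratings)
    if (anyNA(m)) stop("ratings must be complete (no missing values)")
    if (!all(m %in% c(0, 1)))
        stop("ratings must be binary (0 = absent, 1 = present)")
    storage.mode(m) <- "integer"
    m
}

#' Majority vote over observer ratings
#'
#' A recording is labelled present when at least `ceiling(k/2)` of the `k`
#' raters judged a pulsatile sound present. Requires an odd rater count (a
#' tie is undefined otherwise).
#'
#' @param ratings recordings x raters binary matrix (1 = present).
#' @return logical vector, one majority label per recording.
#' @examples
#' majorityVote(rbind(c(1, 1, 0), c(0, 0, 0)))  # TRUE FALSE
#' @export
majorityVote <- function(ratings) {
    m <- check_ratings(ratings)
    k <- ncol(m)
    if (k %% 2L == 0L)
        stop("majority vote requires an odd number of raters")
    out <- rowSums(m) >= ceiling(k / 2)
    names(out) <- rownames(m)
    out
}

#' Fleiss kappa for inter-rater agreement
#'
#' Chance-corrected agreement for `n` subjects each rated by the same
#' number `k` of raters: `kappa = (P_bar - P_e) / (1 - P_e)` with
#' per-subject agreement `P_i = sum_j n_ij (n_ij - 1) / (k (k - 1))` and
#' chance agreement `P_e = sum_j p_j^2` over the category proportions
#' `p_j`. The large-sample standard error (Fleiss 1971) yields a Wald 95%
#' confidence interval. When all ratings fall in one category `P_e = 1`
#' and kappa is undefined: the sentinel `NA` is returned with
#' `categoriesUsed = 1`.
#'
#' @param ratings recordings x raters binary matrix (1 = present).
#' @param confLevel confidence level for the interval (default 0.95).
#' @return list with `kappa`, `categoriesUsed`, `pBar` (observed
#'   agreement), `pE` (chance agreement), `se`, `ci` (length 2),
#'   `nSubjects`, `nRaters`.
#' @examples
#' fleissKappa(ratingsFixture())$kappa  # ~0.679
#' @export
fleissKappa <- function(ratings, confLevel = 0.95) {
    m <- check_ratings(ratings)
    n <- nrow(m); k <- ncol(m)
    if (n < 2L) stop("at least 2 subjects are required")
    n1 <- rowSums(m)            # 'present' votes per subject
    n0 <- k - n1
    p1 <- sum(n1) / (n * k)
    p0 <- 1 - p1
    p_e <- p0^2 + p1^2
    p_bar <- mean((n1 * (n1 - 1) + n0 * (n0 - 1)) / (k * (k - 1)))
    cats <- sum(c(p0, p1) > 0)
    if (cats < 2L)
        return(list(kappa = NA_real_, categoriesUsed = cats, pBar = p_bar,
                    pE = p_e, se = NA_real_, ci = c(NA_real_, NA_real_),
                    nSubjects = n, nRaters = k))
    kappa <- (p_bar - p_e) / (1 - p_e)
    pj <- c(p0, p1)
    q <- sum(pj * (1 - pj))
    se <- sqrt(2 / (n * k * (k - 1))) *
        sqrt(q^2 - sum(pj * (1 - pj) * (1 - 2 * pj))) / q
    z <- stats::qnorm(1 - (1 - confLevel) / 2)
    list(kappa = kappa, categoriesUsed = cats, pBar = p_bar, pE = p_e,
         se = se, ci = c(kappa - z * se, kappa + z * se),
         nSubjects = n, nRaters = k)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct score as a cutoff (a positive call is
#' `score >= cutoff`, since a higher detector score indicates pulsatility),
#' computes sensitivity and specificity at each, and integrates the curve
#' by the trapezoidal rule. With tied scores this equals the rank-based
#' (midrank) Mann-Whitney probability
#' `P(score_pos > score_neg) + P(tie) / 2`.
#'
#' @param scores numeric detector scores (e.g. PTCI_max), one per
#'   recording.
#' @param labels logical (or 0/1) reference labels; both classes must be
#'   present.
#' @return list with `thresholds` (descending; `Inf` first), `sensitivity`
#'   and `specificity` (proportions in \[0, 1\], one per threshold), and
#'   `auc`.
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
        stop("scores and labels must be complete and of equal length")
    if (!any(labels) || all(labels))
        stop("both classes must be represented in the labels")
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    pos <- sum(labels); neg <- sum(!labels)
    sens <- spec <- numeric(length(thr))
    for (i in seq_along(thr)) {
        call <- scores >= thr[i]
        sens[i] <- sum(call & labels) / pos
        spec[i] <- sum(!call & !labels) / neg
    }
    fpr <- 1 - spec
    auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc)
}

#' Sensitivity and specificity at a cutoff
#'
#' Positive call iff `score >= cutoff`; results in percent. `cutoff` may be
#' a vector, giving a cutoff table in the conventional layout (one row per
#' cutoff).
#'
#' @param scores,labels as in [rocAuc()].
#' @param cutoff one or more score cutoffs.
#' @return data.frame with columns `cutoff`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
sensSpecAt <- function(scores, labels, cutoff) {
    labels <- as.logical(labels)
    if (!any(labels) || all(labels))
        stop("both classes must be represented in the labels")
    res <- t(vapply(cutoff, function(ct) {
        call <- scores >= ct
        c(100 * sum(call & labels) / sum(labels),
          100 * sum(!call & !labels) / sum(!labels))
    }, numeric(2)))
    data.frame(cutoff = cutoff, sensitivity_pct = res[, 1],
               specificity_pct = res[, 2])
}

#' Reconstructed 36-recording observer-rating table
#'
#' The three-observer binary rating table implied by the published
#' per-recording vote histogram of the 36-patient study: 20 recordings
#' with three "present" votes, 1 with two, 7 with one, and 8 with none
#' (28 unanimous cases; majority present in 21, absent in 15). The
#' assignment of which rater dissents within the split cases is arbitrary;
#' the majority vote and Fleiss kappa are invariant to it. The same table
#' ships as `inst/extdata/observer_ratings_reconstructed.csv`.
#'
#' @return 36 x 3 integer matrix with recording ids `R01..R36` and rater
#'   ids `rater_1..rater_3`.
#' @export
ratingsFixture <- function() {
    m <- rbind(
        matrix(1L, 20, 3),                                 # 3-yes x 20
        matrix(c(1L, 1L, 0L), 1, 3, byrow = TRUE),         # 2-yes x 1
        matrix(rep(c(1L, 0L, 0L), 7), 7, 3, byrow = TRUE), # 1-yes x 7
        matrix(0L, 8, 3))                                  # 0-yes x 8
    dimnames(m) <- list(sprintf("R%02d", 1:36), paste0("rater_", 1:3))
    m
}

#' Read / write observer-rating CSV
#'
#' Layout: a `recording_id` column followed by one binary column per rater.
#'
#' @param path CSV file path.
#' @param ratings recordings x raters matrix.
#' @return `readRatings` returns the rating matrix with recording ids as
#'   row names; `writeRatings` the path, invisibly.
#' @export
readRatings <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"recording_id" %in% names(df))
        stop("ratings CSV must have a recording_id column")
    m <- as.matrix(df[, setdiff(names(df), "recording_id"), drop = FALSE])
    rownames(m) <- df$recording_id
    check_ratings(m)
}

#' @rdname readRatings
#' @export
writeRatings <- function(ratings, path) {
    m <- check_ratings(ratings)
    df <- data.frame(recording_id = rownames(m) %||%
                         sprintf("R%02d", seq_len(nrow(m))), m,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
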