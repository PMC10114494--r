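#' Generate a matched case-control subset
#'
#' Samples `n_cases` cases without replacement with odds increasing in
#' subject density through a logistic link (`slope` log-odds per VAS point,
#' centred at 50), then greedily matches each case with
#' `controls_per_case` remaining subjects closest in age. With `slope = 0`
#' case status is independent of density and the top-versus-bottom quintile
#' odds ratio is centred at 1.
#'
#' @param subjects A `density_cohort` or its `subjects` data frame
#'   (`subject_id`, `density`, `age`).
#' @param slope Log-odds increase in case probability per VAS density point.
#' @param n_cases Number of cases.
#' @param controls_per_case Matched controls per case (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `is_case`, `match_group`;
#'   each match group holds exactly one case and `controls_per_case`
#'   controls.
#' @export
generate_case_control <- function(subjects, slope, n_cases,
                                  controls_per_case = 3L, seed = 1L) {
  if (inherits(subjects, "density_cohort")) subjects <- subjects$subjects
  stopifnot(all(c("subject_id", "density", "age") %in% names(subjects)))
  n <- nrow(subjects)
  need <- n_cases * (1L + controls_per_case)
  if (need > n) {
    stop(sprintf("insufficient subjects: need %d (cases + matched controls), have %d",
                 need, n), call. = FALSE)
  }
  with_seed(seed, {
    odds <- exp(slope * (subjects$density - 50))
    case_idx <- sample.int(n, n_cases, prob = odds)
    pool <- setdiff(seq_len(n), case_idx)
    groups <- vector("list", n_cases)
    for (g in seq_len(n_cases)) {
      ci <- case_idx[g]
      ord <- pool[order(abs(subjects$age[pool] - subjects$age[ci]))]
      ctrl <- ord[seq_len(controls_per_case)]
      pool <- setdiff(pool, ctrl)
      groups[[g]] <- data.frame(
        subject_id = subjects$subject_id[c(ci, ctrl)],
        is_case = c(TRUE, rep(FALSE, controls_per_case)),
        match_group = sprintf("G%04d", g),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, groups)
  })
}
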