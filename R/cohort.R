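# Cohort bookkeeping: one row per scan with subject, risk/outcome group,
# sex, acquisition site and age at scan. The table drives the statistical
# design; its invariants are enforced at load time.

GROUP_LEVELS <- c("LR-", "HR-", "HR+")
VISIT_LEVELS <- c("V06", "V12", "V24")

#' Validate a cohort table
#'
#' Checks the invariants every downstream stage relies on: unique
#' `(subject_id, visit)` pairs, known group/sex/visit labels, positive ages,
#' and group/sex/site constant within subject.
#'
#' @param df data.frame with columns `subject_id`, `group`, `sex`, `site`,
#'   `visit`, `age_days` (and optionally `t1_path`, `t2_path`).
#' @return The validated data.frame, with class `gm_cohort` prepended.
#' @export
as_cohort <- function(df) {
  req <- c("subject_id", "group", "sex", "site", "visit", "age_days")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  df$site <- as.character(df$site)
  df$visit <- as.character(df$visit)
  if (nrow(df)) {
    bad_g <- setdiff(unique(df$group), GROUP_LEVELS)
    if (length(bad_g)) stop("unknown group label(s): ",
                            paste(bad_g, collapse = ", "))
    bad_v <- setdiff(unique(df$visit), VISIT_LEVELS)
    if (length(bad_v)) stop("unknown visit label(s): ",
                            paste(bad_v, collapse = ", "))
    if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
    if (any(!is.finite(df$age_days)) || any(df$age_days <= 0))
      stop("age_days must be positive")
    key <- paste(df$subject_id, df$visit)
    if (anyDuplicated(key))
      stop("duplicate (subject_id, visit) pair(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    per <- split(df[c("group", "sex", "site")], df$subject_id)
    cst <- vapply(per, function(s) nrow(unique(s)) == 1L, logical(1))
    if (!all(cst))
      stop("group/sex/site must be constant within subject: ",
           paste(names(per)[!cst], collapse = ", "))
    tab <- table(df$subject_id)
    if (any(tab > 3L))
      stop("subjects may have at most 3 scans (one per visit)")
  }
  class(df) <- unique(c("gm_cohort", class(df)))
  df
}

#' Read a cohort CSV
#'
#' Expected header: `subject_id,group,sex,site,visit,age_days` with optional
#' `t1_path,t2_path` image columns. Groups are `LR-`, `HR-`, `HR+`; visits
#' `V06`, `V12`, `V24`.
#'
#' @param path CSV file path.
#' @return A validated `gm_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    for (cc in c("subject_id", "group", "sex", "site", "visit"))
      if (is.null(df[[cc]])) df[[cc]] <- character(0)
    if (is.null(df$age_days)) df$age_days <- numeric(0)
  }
  as_cohort(df)
}

#' Write a cohort table to CSV
#' @param cohort a `gm_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Summarise a cohort
#'
#' Scan counts per group and visit, participant counts, and the percentage
#' of participants with exactly one, two and three timepoints.
#'
#' @param cohort a `gm_cohort`.
#' @return A list with `n_scans`, `n_participants`, `scans_by_group_visit`
#'   (group x visit table), `participants_by_group`, and
#'   `pct_timepoints` (named percentages for 1/2/3 visits).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "gm_cohort"))
  if (nrow(cohort) == 0L)
    return(list(n_scans = 0L, n_participants = 0L,
                scans_by_group_visit = table(factor(character(0), GROUP_LEVELS),
                                             factor(character(0), VISIT_LEVELS)),
                participants_by_group = table(factor(character(0), GROUP_LEVELS)),
                pct_timepoints = c(`1` = NaN, `2` = NaN, `3` = NaN)))
  g <- factor(cohort$group, GROUP_LEVELS)
  v <- factor(cohort$visit, VISIT_LEVELS)
  per_subj <- table(cohort$subject_id)
  subj_group <- factor(vapply(split(cohort$group, cohort$subject_id),
                              `[`, character(1), 1L), GROUP_LEVELS)
  ntp <- table(factor(per_subj, levels = 1:3))
  list(n_scans = nrow(cohort),
       n_participants = length(per_subj),
       scans_by_group_visit = table(g, v),
       participants_by_group = table(subj_group),
       pct_timepoints = setNames(100 * as.numeric(ntp) / length(per_subj),
                                 names(ntp)))
}
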