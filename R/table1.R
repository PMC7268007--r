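#' Load the packaged per-patient clinical and neuropsychological table
#'
#' Returns the per-patient table of demographic, clinical and cognitive
#' data for the 37 unilateral mTLE patients (19 left-focus, 18
#' right-focus): gender, age, education level, handedness (Edinburgh
#' quotient), focus laterality, hippocampal-sclerosis flag, left/right
#' hippocampal volumes in cm^3, age at seizure onset, epilepsy duration,
#' monthly seizure-frequency range (kept as text, e.g. `"15-30"`), number
#' of antiepileptic drugs, IQ, executive scores (z), and language and
#' memory scores (fluency and naming as z; VCI/AMI/VMI as standardized
#' composite indices, mean 100, SD 15). Group mean rows are not stored:
#' they recompute from the per-patient rows (see [table1_means()]).
#'
#' The file's MD5 checksum is verified at load time.
#'
#' @return Tibble with 37 rows and a `group` column
#'   (`"L_mTLE"`/`"R_mTLE"`) derived from `ez_laterality`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_mtle.tsv", package = "lmnet", mustWork = TRUE)
  sum_seen <- unname(tools::md5sum(path))
  if (!identical(sum_seen, .table1_md5)) {
    stop("table1 fixture checksum mismatch: expected ", .table1_md5,
         ", got ", sum_seen, call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  df$group <- ifelse(df$ez_laterality == "Left", "L_mTLE", "R_mTLE")
  tibble::as_tibble(df)
}

.table1_md5 <- "5fdde9c369c4506ad6a8fc3a5f0de327"

#' Recompute the group mean rows of the patient table
#'
#' @param table1 Table from [load_table1()].
#' @return Tibble with one row per group: means of every numeric column
#'   (seizure-frequency ranges are text and are not averaged).
#' @export
table1_means <- function(table1 = load_table1()) {
  table1 |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean), .groups = "drop")
}

#' Group comparison battery on the patient table
#'
#' Runs the between-group (left-focus vs right-focus) Mann-Whitney U tests
#' on the clinical variables and cognitive scores, and the within-group
#' paired t tests contrasting left and right hippocampal volumes. In every
#' U test the left-focus group is the first sample. The dysfunctional /
#' healthy hippocampus comparisons contrast each group's focus-side (resp.
#' contralateral) volume.
#'
#' @param table1 Table from [load_table1()].
#' @return A list of tibbles: `u_tests` (one row per comparison) and
#'   `paired_t` (left vs right hippocampal volume within each group).
#' @export
table1_stats <- function(table1 = load_table1()) {
  l <- table1[table1$group == "L_mTLE", ]
  r <- table1[table1$group == "R_mTLE", ]
  u_vars <- c(age = "age", education_level = "education_level",
              epilepsy_duration = "epilepsy_duration", n_aeds = "n_aeds",
              vol_hippo_l = "vol_hippo_l", vol_hippo_r = "vol_hippo_r",
              iq = "iq", ef_total = "ef_total",
              naming = "naming", semantic_fluency = "semantic_fluency",
              phono_fluency = "phono_fluency",
              vci = "vci", ami = "ami", vmi = "vmi")
  u_tests <- purrr::map_dfr(names(u_vars), function(v) {
    mann_whitney_u(l[[u_vars[[v]]]], r[[u_vars[[v]]]], comparison = v)
  })
  u_tests <- dplyr::bind_rows(
    u_tests,
    mann_whitney_u(l$vol_hippo_l, r$vol_hippo_r, "dysfunctional_hippocampus"),
    mann_whitney_u(l$vol_hippo_r, r$vol_hippo_l, "healthy_hippocampus")
  )
  pt <- dplyr::bind_rows(
    paired_t(l$vol_hippo_l, l$vol_hippo_r, "L_mTLE left vs right hippocampus"),
    paired_t(r$vol_hippo_r, r$vol_hippo_l, "R_mTLE right vs left hippocampus")
  )
  list(u_tests = u_tests, paired_t = pt)
}
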