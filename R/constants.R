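# Shared constants: education stages, SSP level assignments, scenario-matrix
# admissibility, and urbanization upper-limit rules. Everything table-driven so
# tests can assert the grids directly.

#' Education stages
#'
#' The seven education stages carried by the projection, coded 1--7 internally
#' and `E0`--`E6` in output files: illiterate, primary school, junior high
#' school, senior high school, college, bachelor's degree, master's and above.
#' `entry_age` is the age at which a person can first belong to the stage.
#'
#' @return A tibble with columns `edu`, `code`, `label`, `entry_age`.
#' @export
#' @examples
#' education_stages()
education_stages <- function() {
  tibble::tibble(
    edu = 1:7,
    code = paste0("E", 0:6),
    label = c("illiterate", "primary", "junior_high", "senior_high",
              "college", "bachelor", "master_plus"),
    entry_age = c(0L, 6L, 13L, 16L, 19L, 19L, 23L)
  )
}

#' Education progression transitions
#'
#' The stage-progression DAG: a linear chain through senior high school, which
#' then branches into college and bachelor tracks, with bachelor feeding
#' master's. `gate_age` is the age (in the *previous* year) at which the
#' transition is applied, so graduates land at the destination stage's entry
#' age. `cap` is the policy ceiling on each progression rate: 99.9% for the
#' compulsory-education transitions, 30% for senior-to-college, 60% for
#' senior-to-bachelor and 30% for entry into graduate study.
#'
#' @return A tibble with columns `edge`, `from`, `to`, `gate_age`, `cap`,
#'   `label`.
#' @export
#' @examples
#' education_transitions()
education_transitions <- function() {
  tibble::tibble(
    edge = 1:6,
    from = c(1L, 2L, 3L, 4L, 4L, 6L),
    to   = c(2L, 3L, 4L, 5L, 6L, 7L),
    gate_age = c(5L, 12L, 15L, 18L, 18L, 22L),
    cap = c(0.999, 0.999, 0.999, 0.30, 0.60, 0.30),
    label = c("primary_enrolment", "primary_to_junior", "junior_to_senior",
              "senior_to_college", "senior_to_bachelor", "bachelor_to_master")
  )
}

#' SSP demographic level assignments
#'
#' The level (low/medium/high) assigned to each demographic component under the
#' five shared socioeconomic pathways. Education under SSP4 is
#' `income_dependent`: provinces follow the high/medium/low education path
#' according to their high/medium/low income category.
#'
#' @return A tibble with one row per SSP and columns `ssp`, `fertility`,
#'   `mortality`, `migration`, `education`.
#' @export
#' @examples
#' ssp_levels()
ssp_levels <- function() {
  tibble::tibble(
    ssp = paste0("SSP", 1:5),
    fertility = c("low", "medium", "high", "low", "low"),
    mortality = c("low", "medium", "high", "medium", "low"),
    migration = c("medium", "medium", "low", "medium", "high"),
    education = c("high", "medium", "low", "income_dependent", "high")
  )
}

#' SSP-RCP scenario-matrix probabilities
#'
#' Quantitative plausibility weights for combining each SSP with each
#' representative concentration pathway (RCP, the source of the coarse
#' urban-fraction grids used in downscaling). Only pairs with nonzero
#' probability (15 of the 20) are admissible for a downscaling run.
#'
#' @return A tibble with columns `ssp`, `rcp`, `probability`.
#' @export
#' @examples
#' dplyr::filter(ssp_rcp_matrix(), probability > 0)
ssp_rcp_matrix <- function() {
  rcps <- c("RCP2.6", "RCP4.5", "RCP6", "RCP8.5")
  prob <- rbind(
    c(0.0909, 0.4545, 0.4545, 0.0000),
    c(0.0000, 0.0909, 0.6818, 0.2273),
    c(0.0000, 0.1667, 0.5000, 0.3333),
    c(0.0000, 0.3704, 0.5556, 0.0741),
    c(0.0000, 0.0741, 0.3704, 0.5556)
  )
  tibble::tibble(
    ssp = rep(paste0("SSP", 1:5), each = 4L),
    rcp = rep(rcps, times = 5L),
    probability = as.vector(t(prob))
  )
}

#' Admissible SSP-RCP pairs
#'
#' @return A tibble of the scenario pairs with nonzero probability.
#' @export
admissible_ssp_rcp <- function() {
  dplyr::filter(ssp_rcp_matrix(), .data$probability > 0)
}

# Default SSP -> urbanization-pace assumption. SSP4 splits by income category.
ssp_urbanization_assumption <- function(ssp, income_category = NULL) {
  base <- c(SSP1 = "fast", SSP2 = "medium", SSP3 = "slow",
            SSP4 = "income_dependent", SSP5 = "fast")
  a <- unname(base[ssp])
  if (is.na(a)) rlang::abort(paste0("unknown ssp: ", ssp))
  if (a != "income_dependent") return(a)
  if (is.null(income_category)) {
    rlang::abort("SSP4 urbanization assumption needs income categories")
  }
  ifelse(income_category == "high", "fast", "slow")
}

match_level <- function(level, allowed = c("low", "medium", "high")) {
  if (!(is.character(level) && length(level) == 1L && level %in% allowed)) {
    rlang::abort(paste0("level must be one of: ", paste(allowed, collapse = ", ")))
  }
  level
}

# Round-half-up used for urban pixel counts ("nearest integer" rule).
round_half_up <- function(x) floor(x + 0.5)
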