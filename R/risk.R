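#' CNA-profile risk classification
#'
#' A CNA profile is the vector of copy-number states over the eight genes
#' and the PAR1 region; a rule set (ordered condition -> group rules with a
#' default, shipped as JSON configuration) maps each profile to a risk group
#' (GR / IR / PR). The published rule content is not reproduced here: the
#' packaged example rule set is illustrative, and reclassification counting
#' against the printed discordance table uses the risk labels printed there.
#' Reporting granularity follows the two-level GR vs IR/PR convention.
#'
#' @name risk-classification
NULL

RISK_GROUPS <- c("GR", "IR", "PR")

#' The nine comparison regions
#' @export
CNA_REGIONS <- c("IKZF1", "CDKN2A", "CDKN2B", "PAX5", "EBF1", "ETV6",
                 "BTG1", "RB1", "PAR1")

#' Load a risk rule set from JSON
#'
#' Format: `{"rules": [{"if": {"<region>": "<state>", ...}, "then": "GR|IR|PR"},
#' ...], "default": "IR"}`. A condition key `"*"` matches when every region
#' has the given state. Conditions are validated at load time.
#'
#' @param path Path to the JSON rule file.
#' @return List with class `risk_rules`.
#' @export
read_rule_set <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$default) || !cfg$default %in% RISK_GROUPS) {
    stop("rule set must declare a default group in ", paste(RISK_GROUPS, collapse = "/"))
  }
  rules <- lapply(cfg$rules, function(r) {
    if (is.null(r$`if`) || is.null(r$then)) {
      stop("malformed rule: each rule needs 'if' and 'then'")
    }
    if (!r$then %in% RISK_GROUPS) stop("unknown risk group: ", r$then)
    cond <- lapply(r$`if`, as.character)
    bad_region <- setdiff(names(cond), c(CNA_REGIONS, "*"))
    if (length(bad_region)) stop("unknown region in rule: ", bad_region[1L])
    bad_state <- setdiff(unlist(cond), CNA_STATES)
    if (length(bad_state)) stop("unknown state in rule: ", bad_state[1L])
    list(cond = cond, then = r$then)
  })
  structure(list(rules = rules, default = cfg$default), class = "risk_rules")
}

#' Classify a CNA profile
#'
#' First matching rule wins; the default applies when none matches.
#'
#' @param profile Named character vector of states over all regions in
#'   [CNA_REGIONS].
#' @param rules A `risk_rules` object from [read_rule_set()].
#' @param granularity `"three"` for GR/IR/PR, `"two"` to pool IR and PR as
#'   `"IR/PR"` (the reporting default).
#' @return Risk group label.
#' @export
classify_profile <- function(profile, rules, granularity = c("two", "three")) {
  granularity <- match.arg(granularity)
  missing <- setdiff(CNA_REGIONS, names(profile))
  if (length(missing)) {
    stop("profile is missing regions: ", paste(missing, collapse = ", "))
  }
  group <- rules$default
  for (r in rules$rules) {
    if (.rule_matches(r$cond, profile)) {
      group <- r$then
      break
    }
  }
  if (granularity == "two" && group %in% c("IR", "PR")) "IR/PR" else group
}

.rule_matches <- function(cond, profile) {
  for (region in names(cond)) {
    if (region == "*") {
      if (!all(profile[CNA_REGIONS] == cond[[region]])) return(FALSE)
    } else if (profile[[region]] != cond[[region]]) {
      return(FALSE)
    }
  }
  TRUE
}

#' Count patients reclassified between two calling modes
#'
#' Counts distinct patients whose risk label differs between the two modes;
#' multiple gene rows for one patient count once.
#'
#' @param records Data frame with a `patient_id` column and one risk-label
#'   column per mode.
#' @param mode_a,mode_b Column names of the two label sets.
#' @return Integer count of distinct reclassified patients.
#' @export
count_reclassified <- function(records, mode_a, mode_b) {
  stopifnot(all(c("patient_id", mode_a, mode_b) %in% names(records)))
  differs <- records[[mode_a]] != records[[mode_b]]
  length(unique(records$patient_id[differs]))
}
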