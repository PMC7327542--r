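# shared fixtures: small hand-built participant tables and reference designs

# the design behind the catalogued scenarios: true difference -0.1 against a
# 10% margin (the experimental treatment is truly inferior by the margin)
catalogue_design <- function(n_per_arm = 400) {
  trial_design(n_per_arm, 0.5, 0.6, margin = 0.1)
}

make_table <- function(assigned, received, outcome, ...) {
  tab <- data.frame(id = seq_along(assigned), assigned = assigned,
                    received = received, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  tab$outcome <- outcome
  class(tab) <- c("participant_table", "data.frame")
  tab
}

# fully adherent toy table: E outcomes {1,1,0,0}, C outcomes {1,1,1,0}
toy_adherent_table <- function() {
  make_table(
    assigned = rep(c("experimental", "control"), each = 4),
    received = rep(c("experimental", "control"), each = 4),
    outcome = c(1, 1, 0, 0, 1, 1, 1, 0)
  )
}

toy_design <- function(n_per_arm = 4) {
  trial_design(n_per_arm, 0.5, 0.5, margin = 0.2)
}
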