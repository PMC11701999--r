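# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (enumeration / expansion) and never call the code paths they check.

uniform_dvh <- function(dose, volume = 60) dvh(dose, volume)

random_dvh <- function(n_bins = 30, max_dose = 80) {
  doses <- sort(stats::runif(n_bins, 1, max_dose))
  # enforce strict increase
  doses <- doses + seq_len(n_bins) * 1e-6
  dvh(doses, stats::runif(n_bins, 0, 10))
}

# AUC by exhaustive enumeration of event/non-event pairs (ties count 1/2)
auc_pair_oracle <- function(predictions, outcomes) {
  pos <- predictions[outcomes == 1]
  neg <- predictions[outcomes == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# gEUD by expanding integer-unit bin volumes into a per-voxel list
eud_expansion_oracle <- function(doses, unit_volumes, n) {
  voxels <- rep(doses, times = unit_volumes)
  mean(voxels^(1 / n))^n
}

# tiny logistic cohort with a known 2x2 structure
two_by_two_data <- function(events_exposed = 10, n_exposed = 20,
                            events_unexposed = 5, n_unexposed = 20) {
  x <- c(rep(1, n_exposed), rep(0, n_unexposed))
  y <- c(rep(1, events_exposed), rep(0, n_exposed - events_exposed),
         rep(1, events_unexposed), rep(0, n_unexposed - events_unexposed))
  data.frame(x = x, y = y)
}

# minimal eligible patient with clean follow-up
basic_patient <- function(id = "P1", arm = "CF", event_visits = NULL,
                          dvh_obj = uniform_dvh(70), ...) {
  v <- if (is.null(event_visits))
    toxicity_visits(c(6, 12, 24, 36, 48, 60), rep(FALSE, 6),
                    rep("none", 6))
  else event_visits
  patient_record(id, arm = arm, dvh = dvh_obj, visits = v, ...)
}
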