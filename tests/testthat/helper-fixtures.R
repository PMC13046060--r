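# Shared fixture builders and brute-force oracles. Everything is generated
# in code; no stored data.

make_record <- function(sv, wkp, patient = "p1", side = "left",
                        filter = 0, volume = 2, true_dose = NA_real_) {
  kidney_record(patient, side, filter, volume, wkp, sv, true_dose)
}

# Simulated records for one condition, true dose fixed at 4 Gy.
make_sim_records <- function(n_kidneys, params, m_sv = 5, volume = 2,
                             filter = 0) {
  lapply(seq_len(n_kidneys), function(i) {
    sim <- simulate_kidney_measurement(4, params, m_sv)
    kidney_record(sprintf("p%05d", i), "left", filter, volume,
                  sim$wkp_dose, sim$sv_doses, 4)
  })
}

# Independent enumeration of all size-k subset RDs via explicit nested
# loops (k <= 3), deliberately avoiding the package's combn-based path.
oracle_rds <- function(rec, k) {
  sv <- rec$sv_doses_gy
  wkp <- rec$wkp_dose_gy
  m <- length(sv)
  out <- numeric(0)
  if (k == 1) {
    for (i in seq_len(m)) out <- c(out, 100 * (sv[i] - wkp) / wkp)
  } else if (k == 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      out <- c(out, 100 * ((sv[i] + sv[j]) / 2 - wkp) / wkp)
  } else if (k == 3) {
    for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) for (l in (j + 1):m)
      out <- c(out, 100 * ((sv[i] + sv[j] + sv[l]) / 3 - wkp) / wkp)
  } else stop("oracle handles k <= 3 only")
  out
}

oracle_curve_sd <- function(records, k) {
  sd(unlist(lapply(records, oracle_rds, k = k)))
}
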