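# shared fixtures built in code

# a small, fast design for unit tests (same structure, fewer wells)
small_design <- function(...) {
  study_design(
    n_samples = 12,
    regions = dplyr::mutate(default_regions(),
                            sample_share = c(4, 4, 4) / 12),
    ...
  )
}

# turn generator ground truth into the pods-table contract
# (inactive pairs are censored at the maximum tested dilution)
truth_pods_tbl <- function(study) {
  dplyr::transmute(
    study$truth_pods, sample_id, endpoint_id,
    pod = ifelse(is.finite(true_pod), true_pod,
                 max(study$design$dilution_ladder)),
    censored = !is.finite(true_pod)
  )
}

# evaluate the generator's noiseless response curve
gen_curve <- function(dilution, ec50, amp, hill, direction = "decrease") {
  1 + ifelse(direction == "increase", 1, -1) * amp / (1 + (ec50 / dilution)^hill)
}

# simple pods table from explicit values
pods_tbl <- function(sample_id, endpoint_id, pod, censored = FALSE) {
  tibble::tibble(sample_id = sample_id, endpoint_id = endpoint_id,
                 pod = pod, censored = censored)
}
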