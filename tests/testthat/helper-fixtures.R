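# Shared fixtures, built once per test run and memoized across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), .fixtures)
  .fixtures[[name]]
}

# small noiseless cohort: exact fiducials, clean delineation
clean_cohort <- function() {
  fixture("clean_cohort",
          synthesize_cohort(8, seed = 7, noise_sd = 0, drift_amp = 0))
}

# small cohort under default noise/drift
noisy_cohort <- function() {
  fixture("noisy_cohort", synthesize_cohort(10, seed = 3))
}

# tiny network specification (fast to build/train; receptive field 37)
tiny_tcn <- function(dropout = 0) {
  tcn_config(n_blocks = 2, channels = 4, kernel_size = 5,
             dilation_base = 3, dropout = dropout, embedding_dim = 6)
}

tiny_spec <- function(input_set = "ecg_demo_params", ...) {
  model_spec(grouping = lead_grouping("electrical"), tcn = tiny_tcn(),
             scalar_branches = list(demographics = c(5), ecg_params = c(5)),
             projection_dim = 8, regressor_hidden = c(8),
             input_set = input_set, ...)
}

# random single-sample batch for a tiny model with window length W
tiny_batch <- function(W = 30, B = 1, seed = 5) {
  withr::with_seed(seed, list(
    groups = list(limb = matrix(stats::rnorm(B * W * 6), B * W, 6),
                  precordial = matrix(stats::rnorm(B * W * 6), B * W, 6)),
    demographics = matrix(stats::rnorm(B * 4), B, 4),
    ecg_params = matrix(stats::rnorm(B * 4), B, 4),
    B = as.integer(B)))
}

# manual cohort row for controlled morphology experiments
manual_row <- function(lvm, heart_rate = 60, amp_scale = 1,
                       record_id = "M1") {
  data.frame(patient_id = record_id, record_id = record_id,
             lvm_truth = lvm, heart_rate = heart_rate,
             amp_scale = amp_scale, ecg_time = "2024-01-01T00:00:00",
             stringsAsFactors = FALSE)
}

# small prepared dataset for training-loop tests (short window => tiny W)
tiny_dataset <- function() {
  fixture("tiny_dataset", {
    co <- synthesize_cohort(60, seed = 19, store_waveforms = FALSE)
    prepare_inputs(co, window = c(-0.06, 0.06), decimate = 2L)
  })
}
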