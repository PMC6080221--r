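# Shared fixtures: all built in code, deliberately small.

# A noiseless, jitter-free subject: deterministic envelopes make
# ground-truth assertions exact.
clean_profile <- function(...) {
  subject_profile(subject_id = "TEST", gain_jitter = 0,
                  force_tremor_sd = 0, ...)
}

# Short protocol so sessions stay light in unit tests.
short_config <- function(repetitions_per_level = 1, ...) {
  acquisition_config(hold_duration = c(2, 2.5), rest_duration = 0.6,
                     repetitions_per_level = repetitions_per_level, ...)
}

# Tiny recording with prescribed emg/force, 200 Hz.
tiny_recording <- function(emg, force, ...) {
  session_recording(emg = emg, force = force, sampling_rate = 200, ...)
}

# Fresh scratch directory per call.
withr_tempdir <- function() {
  d <- tempfile("myograsp-test-")
  dir.create(d)
  d
}

# Small, quickly trainable experiment configuration.
small_experiment <- function(seed = 11, ...) {
  experiment_config(
    n_subjects = 1, seed = seed,
    acquisition = acquisition_config(hold_duration = c(4, 5),
                                     repetitions_per_level = 2),
    hyper = sae_hyperparams(hidden_sizes = c(30, 30), pretrain_iters = 40,
                            head_iters = 60, finetune_iters = 60),
    train_pool = 140, test_pool = 140, train_groups = 100, test_groups = 100,
    ...)
}
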