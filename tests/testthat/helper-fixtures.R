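tf_names_for_test <- function(n) sprintf("tf%02d", seq_len(n))

# quick regulon-table constructor
reg_df <- function(regulator, target, effect = "activation") {
  data.frame(regulator = regulator, target = target,
             effect = rep_len(effect, length(regulator)),
             stringsAsFactors = FALSE)
}

# compact study spec for pipeline-level tests
small_spec <- function(seed = 1L, ...) {
  study_spec(n_tfs = 12, n_genes = 80, tf_target_density = 0.06,
             tf_tf_density = 0.1, n_sole_targets = 6,
             n_reference_samples = 50, n_imodulons = 8,
             plate_spec = plate_spec(n_wells = 40, n_control_wells = 8,
                                     n_timepoints = 96),
             seed = seed, ...)
}

# a hand-built plate with constant traces (smoothing leaves them unchanged)
constant_plate <- function(maxima, n_control, n_timepoints = 60) {
  n <- length(maxima)
  wells <- data.frame(
    well = sprintf("W%02d", seq_len(n)),
    substrate = c(rep("negative_control", n_control),
                  sprintf("s%02d", seq_len(n - n_control))),
    category = c(rep("control", n_control), rep("N", n - n_control)),
    is_control = c(rep(TRUE, n_control), rep(FALSE, n - n_control)),
    stringsAsFactors = FALSE)
  sig <- matrix(rep(maxima, n_timepoints), n, n_timepoints)
  rownames(sig) <- wells$well
  structure(list(wells = wells, signal = sig,
                 timepoints = seq_len(n_timepoints)),
            class = "plate_kinetics")
}
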