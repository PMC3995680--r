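# Shared fixtures, all built in code.

# single-axis sinusoid recording (x axis), amplitude in mg. The default
# phase offsets the sample grid from the sinusoid's nodes: at 4 Hz and 32 Hz
# there are only 8 samples per cycle, and a node-aligned grid biases the
# discrete rectified mean ~5% below the continuous 2A/pi; a pi/16 offset
# makes the 8-point average representative of the continuous value.
sine_recording <- function(freq_hz, amp_mg, duration_s = 60, fs = 32,
                           offset = 0, phase = pi / 16) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  triaxial_recording(offset + amp_mg * sin(2 * pi * freq_hz * t + phase),
                     rep(0, length(t)), rep(0, length(t)),
                     sampling_rate_hz = fs)
}

# a bout whose epochs have planted USA/FSA ratios (FSA fixed at 100 mg)
planted_bout <- function(ratios, true_class, subject_id = "S1",
                         activity = "x") {
  activity_bout(subject_id, activity, true_class,
                epoch_features(seq_along(ratios) - 1L, 320L,
                               usa_mg = 100 * ratios, fsa_mg = 100,
                               ratio = ratios))
}

# analog Butterworth second-order high-pass magnitude |H(f)|
analog_hp_gain <- function(f, fc = 0.7) {
  r <- (f / fc)^2
  r / sqrt(1 + r^2)
}
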