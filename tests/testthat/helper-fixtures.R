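# Shared fixtures: the two alpha-synuclein reference parameter sets used
# throughout the tests, sample metadata, and small numeric utilities.

a30p_params <- function() {
  md_params(A = 0.0156, B = 0.24, C = 50,
            T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
}

# Extended-variant parameter set: slopes 0.07 / 0.29 below and above the
# slope-change point, onset ramp from E_a = 4.7 kJ/mol (T_fn = 0.782).  The
# jump size is fixed by requiring n(T_fn2) = 0.030.
e46k_params <- function(delta = NULL) {
  mk <- function(d) md_params("extended", A = 0.0058, B1 = 0.07, B2 = 0.29,
                              C = 36, T_fn_onset = 0.782, T_fn0 = 0.828,
                              T_fn1 = 0.875, T_fnx = 0.903, T_fn2 = 0.959,
                              delta = d)
  if (is.null(delta)) delta <- 0.030 - md_evaluate(mk(0), 0.959)
  mk(delta)
}

asyn_wt <- function() {
  read_fasta(system.file("extdata", "alpha_synuclein_wt.fasta",
                         package = "hydromelt"))
}

a30p_sample <- function() sample_info(apply_mutation(asyn_wt(), "A30P"), 50)
e46k_sample <- function() sample_info(apply_mutation(asyn_wt(), "E46K"), 50)

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# random admissible standard parameter sets for property-style tests
random_std_params <- function() {
  bp <- sort(runif(3, 0.78, 0.99))
  md_params(A = runif(1, 0.002, 0.05), B = runif(1, 0, 0.5),
            C = runif(1, 0, 80),
            T_fn0 = bp[1], T_fn1 = bp[2], T_fn2 = bp[3])
}
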