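# Regenerates the frozen constants in R/ionic-rest.R: settles the
# Bondarenko port to its quiescent steady state (5000 ms, dt = 1e-4 ms) and
# re-measures the diastolic thresholds. Run from the package root after any
# change to src/bondarenko.cpp, then paste the printed block into
# R/ionic-rest.R and reinstall.
library(cardiomaze)

m <- bondarenko_model()
V <- m$V_rest + 0
eta <- matrix(as.numeric(m$init_state), ncol = 1L)
for (k in 1:5000) cardiomaze:::.ionic_step(m, V, eta, 0, 10000L, 1e-4)

cat(".bdk_rest_V <-", format(V, digits = 10), "\n")
cat(".bdk_rest_state <- c(\n")
cat(paste0("  ", m$state_names, " = ", format(eta[, 1], digits = 9),
           collapse = ",\n"))
cat(")\n")
cat(".bdk_stim_default <-", round(2 * find_threshold(bondarenko_model()), 1),
    "\n")
cat(".sur_stim_default <-", round(2 * find_threshold(surrogate_model()), 1),
    "\n")
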