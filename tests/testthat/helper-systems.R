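# Shared fixtures: the standard simulation conditions (1 mM lipid in 1 dm^3,
# POPC-like bilayer, 1 uM total solute) and small helpers used across tests.

std_geom <- function(ro_nm = 100) vesicle_geometry(ro_nm = ro_nm)

std_neutral <- function(KP = 1, geom = std_geom()) {
  neutral_params(KP = KP, kloi = 1, geom = geom)
}

std_weak_acid <- function(KPSH = 1, KPSD = KPSH, pKaSw = 7,
                          geom = std_geom()) {
  weak_acid_params(KPSH = KPSH, KPSD = KPSD, pKaSw = pKaSw, kloiSH = 1,
                   geom = geom)
}

nST_std <- 1e-6 # mol, 1 uM in 1 dm^3

# random valid geometry inputs for property-style tests
random_geometry_inputs <- function(n, seed = 421) {
  set.seed(seed)
  data.frame(ro_nm = exp(runif(n, log(20), log(5000))),
             h_nm = runif(n, 3, 5),
             cL_M = 10^runif(n, -5, -2.2),
             VT_dm3 = exp(runif(n, log(0.1), log(10))))
}
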