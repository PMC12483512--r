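# shared fixtures: reference parameter set of the affinity scans
# (nucleus 1 um^3, E_DBD = 15 kT, E_B = 10 kT, V1 = 1 bp^3, d = sqrt(50) bp)
ref_energy <- function(E_B = 10, E_DBD = 15) {
  energy_model(E_B, E_DBD, V1 = 1, V = nm3_to_bp3(1e9))
}
ref_d <- sqrt(50)

# small square-well system used for the Monte Carlo cross-checks:
# V1 = 4/3 pi 2^3 bp^3 (well radius 2 bp), cell 50^3 bp^3, spacing 7 bp
mc_energy <- function(E_B, E_DBD) {
  energy_model(E_B, E_DBD, V1 = 4 / 3 * pi * 8, V = 125000)
}
mc_d <- 7

# sum all R-enumerated configuration weights, split by DBD state
enum_weight_sums <- function(arch, lay, en) {
  cfgs <- enumerate_configurations(arch, lay)
  w <- vapply(seq_len(nrow(cfgs)), function(i) {
    configuration_weight(cfgs$dbd_bound[i], cfgs$matching[[i]], arch, lay, en)
  }, 0)
  list(tf = sum(w[cfgs$dbd_bound]), other = sum(w[!cfgs$dbd_bound]),
       total = sum(w), n = nrow(cfgs))
}
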