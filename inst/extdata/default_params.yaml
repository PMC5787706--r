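# Default kinetic parameterization of the four-gene galactose network.
#
# Per-gene block:
#   alpha        leaky transcription rate, mRNA/min (promoter OFF)
#   delta_alpha  additional transcription when the promoter is ON, so the
#                ON-state rate is alpha + delta_alpha
#   beta         mRNA degradation rate, 1/min (lifetime 10-20 min)
#   gamma        translation rate, protein per mRNA per min
#   mu           protein degradation/dilution rate, 1/min (~2 h doubling)
#   n_sites      strong activator binding sites in the promoter
#
# Shared block:
#   k0_on, k0_off  basal promoter switching rates, 1/min
#   K1, K3, K80    effective constants (molecules) for activated Gal1p,
#                  activated Gal3p and Gal80p dimers
#   Kgal           galactose half-activation concentration, % w/v
#   nu_mat         reporter fluorophore maturation rate, 1/min
#
# The GAL3 gamma shown corresponds to a GAL3 strength
# rho_Gal3 = alpha3*gamma3/(beta3*mu3*K3) = 140 (gradual at 0.5% galactose);
# use set_rho_kgal() / read_params() + set_rho_kgal() to re-target it.
GAL1:
  alpha: 0.01
  delta_alpha: 0.2
  beta: 0.05
  gamma: 1.0
  mu: 0.006
  n_sites: 1
GAL3:
  alpha: 0.015
  delta_alpha: 0.6
  beta: 0.05
  gamma: 2.8
  mu: 0.006
  n_sites: 1
GAL80:
  alpha: 0.06
  delta_alpha: 0.06
  beta: 0.05
  gamma: 0.5
  mu: 0.006
  n_sites: 1
REPORTER:
  alpha: 0.04
  delta_alpha: 4.0
  beta: 0.1
  gamma: 1.0
  mu: 0.006
  n_sites: 1
shared:
  k0_on: 3.0e-05
  k0_off: 0.005
  K1: 10.0
  K3: 1.0
  K80: 25.0
  Kgal: 0.055
  nu_mat: 0.15
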