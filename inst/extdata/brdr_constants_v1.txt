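# cardiowave membrane-model constant table, format_version 1
#
# Beeler-Reuter ventricular action potential model with the
# Drouhard-Roberge reformulation of the fast inward sodium current.
# One "key = value" pair per line; '#' starts a comment.
#
# Rate functions use the canonical form
#   rate(V) = (C1*exp(C2*(V+C3)) + C4*(V+C5)) / (exp(C6*(V+C3)) + C7)   [ms^-1]
# with an optional removable singularity: within 1e-6 mV of singular_V the
# stored analytic (L'Hopital) limit singular_limit is returned.

format_version = 1

# --- membrane constants -------------------------------------------------
# sodium conductance (Drouhard-Roberge), mS/cm^2
g_Na = 15.0
# sodium reversal potential (Drouhard-Roberge), mV
E_Na = 40.0
# background sodium conductance (Beeler-Reuter), mS/cm^2
g_NaC = 0.003
# slow-inward (calcium) conductance, mS/cm^2
g_s = 0.09
# membrane capacitance, uF/cm^2
C_m = 1.0
# intracellular calcium floor, mol/L (keeps ln(Cai) in E_s finite)
cai_floor = 1e-10
# initial calcium before the rest-state solve, mol/L
cai_init = 2e-7

# --- sodium activation m (Drouhard-Roberge) -----------------------------
# alpha_m = 0.9*(V+42.65) / (1 - exp(-0.22*(V+42.65)))
alpha_m.C1 = 0
alpha_m.C2 = 0
alpha_m.C3 = 42.65
alpha_m.C4 = -0.9
alpha_m.C5 = 42.65
alpha_m.C6 = -0.22
alpha_m.C7 = -1
alpha_m.singular_V = -42.65
alpha_m.singular_limit = 4.090909090909091
# beta_m = 1.437*exp(-0.085*(V+39.75))
beta_m.C1 = 1.437
beta_m.C2 = -0.085
beta_m.C3 = 39.75
beta_m.C4 = 0
beta_m.C5 = 0
beta_m.C6 = 0
beta_m.C7 = 0

# --- sodium inactivation h (Drouhard-Roberge) ---------------------------
# alpha_h = 0.1*exp(-0.193*(V+79.65))
alpha_h.C1 = 0.1
alpha_h.C2 = -0.193
alpha_h.C3 = 79.65
alpha_h.C4 = 0
alpha_h.C5 = 0
alpha_h.C6 = 0
alpha_h.C7 = 0
# beta_h = 1.7 / (exp(-0.095*(V+20.5)) + 1)
beta_h.C1 = 1.7
beta_h.C2 = 0
beta_h.C3 = 20.5
beta_h.C4 = 0
beta_h.C5 = 0
beta_h.C6 = -0.095
beta_h.C7 = 1

# --- slow sodium inactivation j (Beeler-Reuter; off by default) ---------
# alpha_j = 0.055*exp(-0.25*(V+78)) / (exp(-0.2*(V+78)) + 1)
alpha_j.C1 = 0.055
alpha_j.C2 = -0.25
alpha_j.C3 = 78
alpha_j.C4 = 0
alpha_j.C5 = 0
alpha_j.C6 = -0.2
alpha_j.C7 = 1
# beta_j = 0.3 / (exp(-0.1*(V+32)) + 1)
beta_j.C1 = 0.3
beta_j.C2 = 0
beta_j.C3 = 32
beta_j.C4 = 0
beta_j.C5 = 0
beta_j.C6 = -0.1
beta_j.C7 = 1

# --- slow-inward activation d (Beeler-Reuter) ---------------------------
# alpha_d = 0.095*exp(-0.01*(V-5)) / (exp(-0.072*(V-5)) + 1)
alpha_d.C1 = 0.095
alpha_d.C2 = -0.01
alpha_d.C3 = -5
alpha_d.C4 = 0
alpha_d.C5 = 0
alpha_d.C6 = -0.072
alpha_d.C7 = 1
# beta_d = 0.07*exp(-0.017*(V+44)) / (exp(0.05*(V+44)) + 1)
beta_d.C1 = 0.07
beta_d.C2 = -0.017
beta_d.C3 = 44
beta_d.C4 = 0
beta_d.C5 = 0
beta_d.C6 = 0.05
beta_d.C7 = 1

# --- slow-inward inactivation f (Beeler-Reuter) -------------------------
# alpha_f = 0.012*exp(-0.008*(V+28)) / (exp(0.15*(V+28)) + 1)
alpha_f.C1 = 0.012
alpha_f.C2 = -0.008
alpha_f.C3 = 28
alpha_f.C4 = 0
alpha_f.C5 = 0
alpha_f.C6 = 0.15
alpha_f.C7 = 1
# beta_f = 0.0065*exp(-0.02*(V+30)) / (exp(-0.2*(V+30)) + 1)
beta_f.C1 = 0.0065
beta_f.C2 = -0.02
beta_f.C3 = 30
beta_f.C4 = 0
beta_f.C5 = 0
beta_f.C6 = -0.2
beta_f.C7 = 1

# --- outward-current activation x1 (Beeler-Reuter) ----------------------
# alpha_x1 = 0.0005*exp(0.083*(V+50)) / (exp(0.057*(V+50)) + 1)
alpha_x1.C1 = 0.0005
alpha_x1.C2 = 0.083
alpha_x1.C3 = 50
alpha_x1.C4 = 0
alpha_x1.C5 = 0
alpha_x1.C6 = 0.057
alpha_x1.C7 = 1
# beta_x1 = 0.0013*exp(-0.06*(V+20)) / (exp(-0.04*(V+20)) + 1)
beta_x1.C1 = 0.0013
beta_x1.C2 = -0.06
beta_x1.C3 = 20
beta_x1.C4 = 0
beta_x1.C5 = 0
beta_x1.C6 = -0.04
beta_x1.C7 = 1
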