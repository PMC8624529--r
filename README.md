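# rygbcat

Compartmental absorption–transit modeling of oral drug absorption before
and after Roux-en-Y gastric bypass (RYGB), with metformin as the packaged
case study.

## The problem

RYGB creates a small gastric pouch and excludes the duodenum and proximal
jejunum. Metformin — a hydrophilic cation absorbed ~90% paracellularly,
with permeability falling duodenum > jejunum > ileum and poor colonic
uptake — should therefore be absorbed *less* after surgery; clinically it
is absorbed *more*. This package implements, as tested open code, the
modeling argument that explains the discrepancy: a gut model carrying only
a single jejunally anchored permeability underestimates post-RYGB
absorption, while assigning measured segmental-dependent permeabilities to
the remaining segments predicts the observed exposure without invoking
intestinal adaptation.

It is aimed at biopharmaceutics and PBPK modelers who want an inspectable,
scriptable alternative to black-box gut simulators for
bariatric-surgery questions.

## The model

Nine gut compartments (stomach → ascending colon) in series with
first-order transit `k_t,i = 1/T_i` and permeability-limited absorption

```
ka_i = 2 · Peff_i · ASF_i / R_i ,   R_i = sqrt(V_i / (π L_i))
```

no gastric absorption, one-compartment disposition (`kel = CL/Vd`), and
bioavailability = fraction of dose absorbed. Segmental permeability comes
from rat single-pass intestinal perfusion,

```
Peff = −Q ln(C'out/C'in) / (2π R L)
```

(gravimetric water-flux correction of the concentration ratio), scaled to
human via `Peff,man = 3.6 Peff,rat + 0.03e−4` cm/s, with a Renkin
hindered-diffusion pore model enforcing the 90:10
paracellular:transcellular split. The RYGB transform zeroes the bypassed
segments and shrinks the stomach to a pH-6.4 pouch. One free scalar per
calibrated scenario (a multiplier on the jejunally anchored permeability)
is fitted by bisection to a reference AUC(0–24) anchor; all other PK
metrics are genuine predictions. See the vignette
(`vignettes/metformin-absorption-after-rygb.Rmd`) for the full account.

## Worked example

```r
library(rygbcat)
pipeline <- run_rygb_pipeline()
pipeline
```

```
<rygb_pipeline>
  multipliers: control 0.1303, rygb_adjusted 0.3598
        scenario              metric observed predicted_reference predicted
6  control_obese          cmax_ng_mL   1800.0              1598.2  1439.466
8  control_obese   auc_0_inf_ng_h_mL  11400.0             13050.0 13202.312
9  control_obese    auc_0_24_ng_h_mL  11100.0             12810.0 12809.483
10 control_obese bioavailability_pct     27.8                27.0    27.233
16 rygb_adjusted          cmax_ng_mL   2000.0              1781.5  1897.189
18 rygb_adjusted   auc_0_inf_ng_h_mL  13700.0             15100.0 15267.569
19 rygb_adjusted    auc_0_24_ng_h_mL  13400.0             14830.0 14830.082
20 rygb_adjusted bioavailability_pct     41.8                40.6    40.964
```

(healthy and naive post-RYGB rows elided). Reading the table: each
scenario's AUC(0–24) was anchored by calibration; the remaining rows are
predictions. The control subject (obese, 1000 mg) absorbs ~27% of the
dose; merely bypassing duodenum/jejunum at the control permeability drops
that to ~25% (`rygb_naive` row, elided) — the *wrong* direction — while
the segmental-dependent permeability profile raises post-RYGB
bioavailability to ~41%, matching the observed increase.

Single pieces are available on their own, e.g.

```r
est <- estimate_peff(synth_spip(spip_sim_spec(2.795e-5, noise_cv = 0)), 0.2, 10)
rat_to_human(est$peff)         # 1.036e-4 cm/s
apply_rygb(default_fasted_physiology())
```

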