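# occuPET

Kinetic modelling of dynamic PET for in vivo receptor-occupancy studies.

occuPET is an R package for quantifying dynamic small-animal PET scans of a
receptor-specific radiotracer with arterial blood sampling, and for turning
baseline-versus-pretreatment scans into drug dose–occupancy curves. It is
aimed at preclinical imaging groups running competition (blocking) studies:
the input is tabular — framed tumor time–activity curves, whole-blood and
plasma sample series, intact-tracer (parent) fractions — and the output is
per-scan kinetic parameters, per-dose receptor occupancies and an in vivo
ED50. A synthetic-study generator with known ground truth supports
validation and power exploration.

## The models

Tissue kinetics: one- and two-tissue reversible compartment models driven by
the metabolite-corrected plasma input, with the measured signal mixing tissue
and whole blood through the fractional blood volume,

    C(t) = (1 - Vb) * (h ⊗ Cp)(t) + Vb * Cwb(t),

fitted by bounded weighted nonlinear least squares (Vb estimated, 5
multistarts) and compared by AIC = N ln(WRSS/N) + 2P. Macro-parameters:

    V_T = (K1/k2) (1 + BP_ND),      BP_ND = k3/k4.

Graphical estimators: the Logan plot (late-time slope = V_T, reversible
tracers; default t* = 10 min) and the Patlak plot (slope = net influx Ki;
default t* = 20 min). Metabolite correction multiplies plasma by a population
parent-fraction model f(t) = c + (1-c) e^(-kt).

Occupancy and dose–response:

    Occ_VT = (V_T(base) - V_T(drug)) / (V_T(base) - V_ND) * 100%
    Occ_BP = (BP(base) - BP(drug)) / BP(base) * 100%

with V_ND extrapolated from V_T(D) = V_ND + V_S * ID50/(ID50 + D) across
doses, and ED50 from the Hill regression Occ(D) = Emax D^h/(ED50^h + D^h)
(Emax fixed at 100% by default; fixed-slope and free-plateau variants are
available and documented — the choice matters).

## A worked example

Simulate a full occupancy study (6 baseline rats, 3 per dose at 0.5–60 mg/kg,
21-frame 60-min scans, arterial sampling, realistic frame noise) and run the
whole pipeline — metabolite fit, 1TCM/2TCM fits with AIC selection, Logan
analysis, V_ND extrapolation, occupancy and ED50:

```r
library(occuPET)
study  <- generateStudy(seed = 1)
report <- runStudy(study)
report
```

Abridged output of exactly this call:

```
StudyReport
===========
21 scans analysed, 0 failures
ParentFractionModel: f(t) = 0.01282 + 0.9872 exp(-0.006111 t)  [residual SD 0.0225]

Group summary (mean +/- SD):
 dose n               VT             BP                Vb         VTlogan
  0.0 6  0.862 +/- 0.023   2.79 +/- 1.7  0.0583 +/- 0.015  0.863 +/- 0.02
 30.0 3  0.477 +/- 0.008  0.684 +/- 0.2  0.0644 +/- 0.018 0.509 +/- 0.012
 ...

Occupancy by dose (%):
   method dose occupancy    sd flagged
  VT-2TCM  0.5      4.82  6.13   FALSE
  VT-2TCM 10.0     47.61  1.58   FALSE
  VT-2TCM 60.0     85.76  4.42   FALSE
 ...

ED50 fits:
   method ed50  hill    r2       p reliable
  VT-2TCM 10.3 0.971 0.999 0.00140     TRUE
  BP-2TCM 14.0 1.561 0.864 0.09186    FALSE
 VT-Logan 10.9 0.969 0.998 0.00135     TRUE

Ground-truth comparison:
       quantity  truth estimate relError
    baseline VT  0.870    0.862 -0.00929
  baseline BPND  1.850    2.790  0.50802
    VND (K1/k2)  0.305    0.342  0.11932
 ED50 (VT-2TCM) 12.700   10.287 -0.19001
```

Reading it: baseline V_T is recovered within 1%; V_T falls monotonically with
dose and the V_T-based occupancies from the compartment fit and from Logan
agree within a few points at every dose. The BP_ND column illustrates a real
phenomenon, not a bug: k3/k4 is noise-sensitive (baseline estimate 2.79 vs
truth 1.85, SD 1.7), its dose-dependence fails the significance test
(p = 0.09) and the BP-based ED50 is therefore tagged unreliable — V_T-based
estimates are the ones to use. The single-study ED50 of 10.3 mg/kg scatters
around the generating 12.7 mg/kg; across 25 replicate studies the median
recovers it within a few percent (see the test suite).

Lower-level functions are exported individually: `fitCompartment()`,
`loganVT()`, `patlakKi()`, `fitParentFraction()`/`correctPlasma()`,
`fitBiexponential()`, `fitVND()`, `fitED50()`, `occupancyFromVT()`,
`occupancyFromBP()`, `compareGroups()`, plus readers/writers for the CSV/YAML
formats (`readTAC()`, `readBlood()`, `readParent()`, `readStudy()`, ...).
See the vignette in `vignettes/occupancy-modelling.Rmd` for the models,
numerical choices and the generator's design.

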