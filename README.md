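# hybridbci

Hybrid fNIRS–EEG decoding of auditory and visual perception for passive
brain–computer interfacing.

## What this package does

A passive BCI monitors what a person is perceiving — auditory input, visual
input, both, or neither — from brain signals alone. This package implements,
end to end and fully testable, a complete analysis protocol for that
problem on simultaneous fNIRS + EEG recordings:

* a **synthetic multimodal session generator** reproducing the block design
  (30 trials each of AUD/VIS/MIX/IDLE with 12.5 ± 2.5 s stimuli and
  20 ± 5 s rests, plus three continuous 60 s clips) and the signal
  phenomenology — double-gamma haemodynamic responses at the stimulated
  probe, modality-specific evoked potentials with a P300-like component,
  label-gated occipital alpha (suppressed by visual engagement), cardiac
  pulsation, eye blinks — with known ground truth;
* the **optical preprocessing chain**: AC mean-normalization, data-driven
  cardiac pulse correction, 8 s median filtering with downsampling to 1 Hz,
  modified Beer–Lambert conversion to HbO/HbR concentration changes
  (`dOD_λ = (ε_HbO,λ ΔHbO + ε_HbR,λ ΔHbR) · d · DPF_λ`), and common average
  referencing;
* the **EEG chain**: 0.5–48 Hz zero-phase FIR band-pass, seeded ICA
  eye-blink removal, 100 ms prestimulus baseline correction;
* **four single-trial feature types** — HbO and HbR slope features
  `f_c = (2/w) (Σ_{t_opt}^{t_opt+w/2} x_c(t) − Σ_{t_opt−w/2}^{t_opt} x_c(t))`
  with `(t_opt, w)` selected by nested cross-validation, Welch band power
  (every other 0.5 Hz component in 3–40 Hz; 38 per electrode), and the
  filtered, 13×-downsampled ERP waveform (20 per electrode);
* **classifiers and decision fusion**: shrinkage-regularized LDA
  (`Σ_reg = (1−γ) Σ̂ + γ (tr Σ̂/d) I`, γ = 0.5) for HbO/HbR/POW, a linear
  soft-margin SVM for ERP, and a META classifier
  `p_meta = Σ_m w_m p_m` whose weights are the above-chance evaluation
  accuracies mapped to [0, 1] and normalized to unit sum;
* **evaluation**: five binary conditions (AUD vs VIS, AUD vs IDLE,
  VIS vs IDLE, allAUD = {AUD, MIX} vs nonAUD, allVIS vs nonVIS), nested
  leave-one-trial-out and leave-one-subject-out cross-validation,
  cross-condition transfer (e.g. auditory detectors on MIX trials),
  continuous decoding on 50 %-overlapping windows of 1–16 s, binomial
  chance bounds, and paired META-vs-best tests with Holm correction;
* **reporting**: grand-average HRFs, ERPs and spectra, correlation-based
  electrode/frequency/time-window/probe rankings with Friedman tests, and
  fNIRS best-channel probe localization.

See the methods vignette (`vignettes/hybrid-decoding-methods.Rmd`) for the
models, parameters and design choices.

## A worked example

Simulate a small cohort at the study's trial count (two subjects, 30 trials
per label, 6 fNIRS channels per probe), preprocess it, and run the nested
leave-one-trial-out evaluation for one subject (about a minute in total):

```r
library(hybridbci)

fx  <- make_fixtures(seed = 42, n_subjects = 2, trials_per_label = 30)
rep <- run_subject_dependent_cv(fx$trials[[1]],
                                bci_conditions()[["AUD vs VIS"]],
                                seed = 11)
rep
#> AUD vs VIS [subject-dependent] subject s01, n = 60:
#>   HbO   86.7%
#>   HbR   90.0%
#>   POW  100.0%
#>   ERP   85.0%
#>   META 100.0%
```

Each line is a cross-validated accuracy over the 60 trials for one feature
type (HbO/HbR haemoglobin slopes, EEG band power, EEG evoked waveform) and
for the fused META classifier. All of them sit far above the 99 % chance
upper bound for 60 trials (`chance_upper_bound(60)` = 67.5 %), and META
matches the best individual classifier - the fusion-no-harm property the
acceptance suite checks across a 12-subject cohort.

Where does the information come from? Rank electrodes by the correlation of
their band-power features with the labels:

```r
pow_by_subject <- lapply(fx$trials, function(tr)
  pow_feature(build_condition(tr, bci_conditions()[["VIS vs IDLE"]])))
rank_features(pow_by_subject, "electrode")
#> Average feature ranking by electrode (2 subjects)
#>    1. Oz       mean rank 1.50 (SD 0.71)
#>    2. O1       mean rank 2.00 (SD 1.41)
#>    3. O2       mean rank 2.50 (SD 0.71)
#>    4. Pz       mean rank 4.00 (SD 0.00)
#>    ...
```

The occipital electrodes (Oz, O1, O2) lead the VIS-vs-IDLE ranking - the
planted alpha suppression is where it should be.

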