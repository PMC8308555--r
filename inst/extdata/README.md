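# Packaged instrument fixture

Five genome-wide significant homocysteine-associated variants from Korean
population cohorts (exposure associations: KARE, n = 5902, log-transformed
homocysteine, adjusted for age/sex/area; outcome associations: merged
HEXA + CAVAS metabolic-syndrome logistic ORs, n = 5509, adjusted for
age/sex/study site).

- `hcy_exposure_kare.tsv`: per-allele betas, SEs and p-values transcribed
  verbatim from the published association tables.
- `mets_outcome_hexa_cavas.tsv`: published ORs with 95% CIs. The loader
  `hcy_instruments()` derives `beta = ln(OR)` and
  `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`; these columns are DERIVED,
  not published.
- `eaf` (effect-allele frequency) and `other_allele` are NOT published for
  this panel; values here are approximate East-Asian annotations from
  public variant databases (synthetic annotation) and are used only for
  palindromic-variant screening, which none of these variants triggers.
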