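# ppidisp

Estimate the completely dispensable fraction of protein–protein
interactions (PPIs) — those whose elimination by mutation has no
measurable fitness effect — separately for **transient** and
**permanent** interactions in a structural interactome.

## The problem and the model

Most systems-biology work assumes permanent, stoichiometric PPIs are
functionally important; whether the same holds for weak, short-lived or
non-co-expressed (transient) PPIs is much less clear. `ppidisp`
implements a structure-based pipeline that answers this with a Bayesian
estimator.

Missense mutations are effectively neutral (N), mildly deleterious (M)
or strongly detrimental (S) with priors P(N) = 0.27, P(M) = 0.53,
P(S) = 0.20. Common variants from healthy individuals proxy N; disease
variants proxy M; S-class mutations are assumed quasi-null (they
destabilize the whole protein), so their edgetic rate is 0. For a PPI
group T (say, weak transient PPIs), per-class edgetic disruption rates
P(T|N) and P(T|M) are measured by mapping mutations onto PPI binding
interfaces and calling a disruption when the interfacial binding-energy
change exceeds 0.5 kcal/mol (ΔΔG > 0.5, strict). Then

    P(T)   = P(T|N) P(N) + P(T|M) P(M) + P(T|S) P(S)        (marginal)
    P(N|T) = P(T|N) P(N) / P(T)                             (Bayes)

and P(N|T) — the *dispensable content* of group T — depends on the data
only through the rate ratio:

    1 / P(N|T) = 1 + (P(M)/P(N)) · (P(T|M)/P(T|N))

A 95% CI for P(N|T) comes from the log-scale (Bland) interval for the
ratio of two proportions, mapped through this monotone form.

The package provides the full supporting pipeline:

* **interactome core** — residue-level interface detection (5 Å
  all-atom contact rule), template annotation by ≥ 50% interface-residue
  coverage of E ≤ 1e-5 alignments, mutually-exclusive-interface counting;
* **mutation pipeline** — MAF ≥ 1% filtering, per-position dedupe,
  disease-overlap removal, flanking-sequence position verification,
  interface mapping, ΔΔG attachment;
* **classifiers** — weak/strong by ΔG ≥ −25 kcal/mol; transient/
  permanent in time and space by partner co-expression against
  dataset-median thresholds; stoichiometric (im)balance by mean
  |log10| expression difference; exclusivity bins 0 / 1–4 / ≥5;
* **edgotype engine** — per-mutation disruption calls, edgetic /
  quasi-wild-type / mono-edgetic assignment, per-property count tables;
* **estimator** — the Bayes point estimate, Bland CIs, prior
  sensitivity, and ΔΔG-cutoff robustness sweeps;
* **benchmark metrics** — balanced accuracy, precision, TPR/FPR, exact
  two-sided Fisher test, Kd ↔ ΔG conversion (ΔG = RT ln Kd);
* **synthetic data** — a seeded generator producing a full input bundle
  (toy coordinates consistent with the 5 Å rule, two-class ΔG mixture,
  factor-model expression with known per-pair co-expression targets,
  mutation cohorts with known ground-truth disruption rates).

## Worked example

Using the published per-property disruption counts (bundled as
`reference_counts()`) for the Y2H-derived structural interactome,
weak-transient group — 3/1080 common and 7/348 disease mutations
disrupt a weak PPI:

```r
library(ppidisp)
y2h <- subset(reference_counts(), property == "strength" & si == "Y2H")
rates <- rates_from_counts(y2h, "T")
dispensable_content(rates)
#> $p_t         0.01141   # 1.1% of new missense mutations disrupt a weak PPI
#> $p_n_given_t 0.06573   # 6.6% of weak transient PPIs are dispensable
#> $ratio       0.138
bland_ci(rates)
#> $ci_low  0.0180        # 95% CI ~2–21%
#> $ci_high 0.2130
```

The whole published table reproduces at printed precision:

```r
fa <- format_analysis(run_full_analysis(reference_counts()))
head(fa[fa$property == "strength", ], 4)
#>   property  si group p_t_n_pct p_t_m_pct ratio p_n_given_t_pct ci_low_pct ci_high_pct
#> 1 strength Y2H     T       0.3       2.0  0.15             6.6          2          21
#> 2 strength Y2H     P       1.2      10.3  0.12             5.6          3          10
#> 3 strength Lit     T       0.9       3.2  0.28            12.9          9          19
#> 4 strength Lit     P       1.0       4.3  0.23            10.6          7          15
```

Reading: disease mutations disrupt PPIs far more often than common
ones, but the common:disease rate ratio — hence the dispensable content
(~6–13%, CIs below ~21%) — is similar for transient and permanent
groups.

A fully synthetic end-to-end run:

```r
cfg <- generator_config(seed = 1)        # Y2H-scale world
b   <- generate_bundle(cfg)
labs  <- classify_interactome(b$interactome, b$experiments)
calls <- predict_disruptions(attach_effects(
  b$mutations, locate_interfacial(b$mutations, b$interactome), b$effects))
tab <- tabulate_edgotypes(b$mutations, calls, b$interactome, labs, "strength")
dispensable_content(rates_from_counts(tab, "T"))
# compare with b$ground_truth$analytic_p_n_given_t
```

## Command line

```sh
ppidisp synth    --config cfg.txt --out bundle --seed 7
ppidisp classify --ppis bundle/ppis.tsv --fasta bundle/proteins.fasta \
                 --expr bundle/expression --out labels.tsv
ppidisp edgotype --ppis bundle/ppis.tsv --fasta bundle/proteins.fasta \
                 --mutations bundle/mutations.tsv --ddg bundle/ddg.tsv \
                 --labels labels.tsv --property strength --out counts.tsv
ppidisp estimate --counts counts.tsv --priors 0.27,0.53,0.20 --out disp.tsv
```

(`ppidisp` is installed under `<library>/ppidisp/exec/`.)

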