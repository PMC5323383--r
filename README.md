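# dockscape

Sequence- and structure-guided prioritization of enzyme point mutations,
built around a docking-pose **RMSD–binding-energy landscape** analysis.

## The problem

Rational enzyme engineering needs two answers: *which* residues to mutate,
and *what* to mutate them to. `dockscape` implements a computational funnel
that answers both for enzymes whose product-bound structure is known
(designed around a type-II chalcone–flavonone isomerase, but generic in its
stages):

1. **Subfamily-specific positions (SSPs).** In a protein alignment split
   into two functional subfamilies, an SSP is a column conserved within each
   group but different between them — a classic marker of functional
   divergence. `detect_ssps()` reports them in the numbering of a chosen
   reference sequence.
2. **Positively selected sites.** Sites with high Bayes-empirical-Bayes
   posterior probability of positive selection (dN/dS > 1) from branch-site
   codon models are read from codeml output or TSV and merged with the SSPs
   into the candidate set (`merge_candidates()`).
3. **Structural screen.** `screen_candidates()` keeps candidates whose
   residues lie within a distance cutoff (default 10 Å) of the active site
   and whose side chains do **not** hydrogen-bond directly into the
   catalytic network (heavy-atom N/O–N/O ≤ 3.5 Å).
4. **Mutation panel.** `enumerate_mutations()` proposes one substitution per
   physicochemical class (non-polar, aromatic, polar, basic, acidic; Ala,
   Phe, Gln, His, Glu by default, with within-class alternates such as E→D
   at acidic sites) plus proline at loop sites.
5. **Pose landscape and decision rule.** For each receptor variant, docking
   poses (AutoDock DLG logs or multi-MODEL PDB + energy table) are plotted
   as binding energy vs receptor-frame RMSD to the product pose
   (no superposition):

   RMSD(p, r) = sqrt( (1/N) Σᵢ ‖pᵢ − rᵢ‖² )

   One-dimensional k-means on the RMSD axis splits the ensemble into groups
   I–IV: near-product modes I–III with representative energies
   E(I) > E(II) > E(III), and the flipped orientation IV at RMSD > 6 Å.
   Reading I → II → III as progress from encounter complex toward a
   product-like arrangement, `compare_mutant()` applies the **group-III
   rule**: a mutation that lowers the group-III representative energy by
   more than ε (default 0.5 kcal/mol) is predicted *beneficial* for
   activity, one that raises it *detrimental*, otherwise *neutral*.

A synthetic-data module generates every input with planted truth (SSP
columns, selected sites, screening outcomes, pose modes, mutant energy
shifts), so the whole pipeline is testable offline; `simulate_inputs()`
produces a complete bundle at the 14-homolog / 2,000-pose study scale.

The package consumes the outputs of external tools (aligners, RAxML/PAML,
MODELLER/Rosetta, AutoDock) and never re-implements them.

## Worked example

```r
library(dockscape)
sim    <- simulate_inputs(seed = 3, out_dir = "bundle")  # writes all fixtures
report <- run_pipeline(sim$config, out_dir = "run")
print(report)
```

```
Mutation-design pipeline report
  SSPs detected: 9
  candidate sites: 11
  retained after screen: 4
  designed mutations: 22
  compared mutants (epsilon = 0.50 kcal/mol):
 rank mutation origin delta_e_iii     verdict
    1    I197P    PSD     -1.5415  beneficial
    2    R110A    SSP     -1.2039  beneficial
    3    E107D    SSP     -0.0083     neutral
    4    R110E    SSP      0.5955 detrimental
    5    E107Q    SSP      0.7583 detrimental
    6    R110H    SSP      1.0003 detrimental
```

Reading the output: nine SSP columns plus two positively selected sites give
eleven candidates; the structural screen keeps four (here 107, 110, 196,
197); the panel designs 22 substitutions. For the six mutants with docking
ensembles, `delta_e_iii` is the change in the group-III representative
binding energy relative to wild type — the planted effects (−1.5, −1.2, 0,
+0.6, +0.8, +1.0 kcal/mol) are recovered, the two planted-beneficial mutants
rank first, and the verdict pattern is two beneficial / one neutral / three
detrimental. Per-variant landscapes are available via
`plot(report$landscapes[["I197P"]])`, or overlaid on the wild type with
`plot(report$landscapes[["wild-type"]], overlay = report$landscapes[["I197P"]])`.

Lower-level entry points (`read_alignment()`, `read_selection_table()`,
`read_structure()`, `read_docking_log()`, `cluster_groups()`, ...) expose
each stage separately; `inst/scripts/run-pipeline.R` is a thin command-line
wrapper over `run_pipeline()`. See the methods vignette
(`vignettes/dockscape-methods.Rmd`) for the model, parameter defaults and
the synthetic generator's design.

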