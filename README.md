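# bioactpep

Bioactive peptide prediction and comparative peptidomics in R.

Mucosal secretions, venoms, food hydrolysates and similar biological
samples contain thousands of short peptides, a fraction of which carry
bioactivities — antibacterial, antihypertensive, cell-penetrating,
tumor-homing and so on — that are expensive to establish experimentally.
`bioactpep` screens peptide lists for such candidate activities with
per-property machine-learning classifiers, and compares peptide
repertoires across species to find the conserved core and the
species-specific patterns. It is aimed at proteomics groups who have
peptide identifications (e.g. from LC-MS/MS of secretome samples) and
want a reproducible, scriptable triage of putative bioactivities.

## The method

**Featurization.** Each peptide sequence *s* over the 20 canonical amino
acids (length ≥ 2) is mapped to a 407-element descriptor
*x(s)* = (mass, length, GRAVY, n⁺, n⁻, n⁺−n⁻, f_h, d₁, …, d₄₀₀), where
GRAVY is the mean Kyte–Doolittle hydropathy, n⁺ counts K/R/H, n⁻ counts
D/E, f_h is the fraction of hydrophobic residues (A, V, L, I, M, F, W, C),
and d_XY = #\{adjacent XY pairs\}/(|s|−1) is the ordered dipeptide
composition (400 entries summing to 1).

**Classification.** For every bioactive-property category a labeled
positive/negative peptide set is balanced by random minority
oversampling, split 70%:30% stratified by class, and used to train a
*pair* of classifiers on the identical feature matrix: a k-nearest-
neighbour model (k = 2, Euclidean distance, scalar descriptors z-scored,
deterministic tie rules) and a random forest (1000 trees, mtry =
⌊√407⌋ = 20). Each model is scored on the held-out 30% with the full
confusion-matrix panel: accuracy with its exact Clopper–Pearson 95%
interval, sensitivity, specificity, the no-information rate (NIR, the
largest class prevalence), and the one-sided exact binomial p-value for
accuracy exceeding the NIR. A peptide–property call is a **consensus
positive** when both methods call it positive *and* the property is in
the registry of categories both methods support (11 of the 22-category
vocabulary by default).

**Comparative peptidomics.** From a peptide × (species, replicate)
intensity table: presence per species is the replicate maximum (> 0);
intensities are normalized by per-column mean centering over detected
peptides; a one-way ANOVA screens peptides varying across species
(p < 0.05); peptides present in all species form the **core** set and
the remaining detected peptides the **variable** set; variable
presence/absence profiles are clustered hierarchically and by k-modes
(simple-matching dissimilarity, column-majority modes, default k = 28);
and the pattern × species contingency table is decomposed by
correspondence analysis (SVD of the standardized residuals
S = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}; principal inertias σᵢ², principal
coordinates, square cosines).

A synthetic-data module generates labeled peptide sets with tunable
class separability and abundance matrices with planted core/variable
structure and pattern clusters, so every stage can be verified against
known ground truth.

## Worked example

```r
library(bioactpep)

# train a classifier pair on a synthetic, strongly separable property
s <- gen_labeled_peptides(400, effect = 0.9, seed = 1)
pair <- train_classifier_pair(s, training_config(seed = 1))
pair
#> <classifier_pair 'synthetic'>
#> -- kNN --
#> Accuracy    : 0.9625 (95% CI 0.9300-0.9827)
#> Sensitivity : 0.9583
#> Specificity : 0.9667
#> NIR         : 0.5000   P[acc > NIR] : 3.682e-57
#> Counts      : TP 115  TN 116  FP 4  FN 5
#> -- RF --
#> Accuracy    : 0.9792 (95% CI 0.9521-0.9932)
#> Sensitivity : 0.9833
#> Specificity : 0.9750
#> NIR         : 0.5000   P[acc > NIR] : 3.679e-63
#> Counts      : TP 118  TN 117  FP 3  FN 2

# comparative pipeline on a planted 2818-peptide, 7-species matrix
g <- gen_presence_matrix(n_species = 7, n_core = 1218, n_variable = 1600,
                         n_patterns = 28, noise_sd = 0.5, seed = 1)
pres <- call_presence(g$abundance)
part <- partition_core_variable(pres)
length(part$core); length(part$variable)
#> [1] 1218
#> [1] 1600

pa <- kmodes(pres$presence[part$variable, ], k = 28, seed = 1)
ca <- correspondence_analysis(pattern_contingency(pa, pres))
ca
#> <ca_result: 6 dimensions; total inertia 0.8950>
#>   first two dimensions explain 46.96% of the variation

property_registry()
#> <property_registry: 22 categories; kNN 14, RF 11, consensus 11>
```

The held-out accuracies say both classifiers recover the planted
compositional signal almost perfectly; the partition returns exactly the
planted core (43% of 2818 peptides); and the correspondence analysis
summarizes how the 28 discovered presence patterns distribute over the
seven species, with the first biplot plane carrying about half of the
table's inertia.

A command-line interface over the same functions is installed at
`inst/scripts/bioactpep` with subcommands `featurize`, `train`,
`predict`, `consensus`, `compare` and `simulate`; every run writes a
manifest recording its inputs and seeds.

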