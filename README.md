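# gatddg

Structure-based prediction of mutation-induced protein stability changes
(ΔΔG, kcal/mol), for protein engineers and variant-effect researchers who
want a predictor that treats a mutation A→B and its reversal B→A
consistently (an unbiased predictor satisfies ΔΔG(B→A) = −ΔΔG(A→B)).

## The method

The predictor has two stages.

**1. A self-supervised geometric encoder.** A protein is represented as an
atom graph: heavy atoms (C/N/O/S) within 12.0 Å of the centroid of a
chosen residue are nodes (a residue contributes all of its atoms if any
one is inside the radius), and atom pairs closer than 3.0 Å are edges.
Each node carries a 36-component attribute vector: element one-hot (4),
residue-type one-hot (20), DSSP 8-class secondary-structure one-hot (8),
perturbed-flag one-hot (2), a SASA>0 bit, and a Cα bit. Four stacked
8-head graph-attention layers update node features; per head
*k*, attention logits are

    e_ij = LeakyReLU( a_k · [W_k f_i ‖ W_k f_j] ),  slope 0.2

softmax-normalized over each node's closed neighborhood, and the head
output is ELU(Σ_j α_ij W_k f_j), heads concatenated.

The encoder is pretrained with a side-chain perturbation task: a random
χ-bearing residue's side chain is re-posed at a rotamer sampled from a
rotamer library (means/σ/probabilities; Dunbrack-format files can be
loaded), and a 3-layer MLP head must predict, for every atom *i* of the
perturbed residue, its displacement Δd_i from the native position. The
loss is the mean squared error over the perturbed residue's atoms N_p:

    L = (1/|N_p|) Σ_{i∈N_p} (Δd_i − Δd_i^real)²

Training uses Adam, batch size 128, learning rate 0.001. Glycine and
alanine have no χ angles; their perturbation is the identity with zero
displacement labels. The per-atom geometric representation g_i is the
concatenation of the layer-3 and layer-4 attention outputs.

**2. A pooled-feature boosted-tree ensemble.** For a mutation at one site,
wild-type and mutant graphs are built centered on that residue (the mutant
side chain is placed from idealized template geometry at the library's top
rotamer). With A_m the mutated residue's atoms and A_n the environment
atoms in each graph, the feature vector per layer L ∈ {3,4} is

    F^(L) = std( F_mo ‖ F_no ‖ F_mo−F_no ‖ F_mm ‖ F_nm ‖ F_mm−F_nm )

where each block is [max-pool ‖ mean-pool] over the corresponding atom
set and std(·) is training-set standardization. Then
ΔΔG = XGBoost(F^(3) ‖ F^(4)), where the regressor is a 10-fold ensemble:
ten members each trained on nine folds (hyperparameters grid-searched on
mean validation PCC), predictions averaged. The training set is balanced
by inverse-mutation augmentation: every record A→B with label +ΔΔG yields
a partner B→A with label −ΔΔG, featurized with the wild-type/mutant roles
swapped.

Evaluation covers PCC/RMSE/MAE, stabilizing-vs-destabilizing
classification (ACC/SEN/SPE/MCC; stabilizing = ΔΔG < 0), the
anti-symmetry bias metrics r^{d−i} = PCC(pred_direct, pred_inverse) and
⟨δ⟩ = mean(pred_direct + pred_inverse), and SNV / non-SNV stratification
(substitutions reachable by one nucleotide change under the standard
genetic code).

## Worked example

```r
library(gatddg)

# synthetic fixture data: ideal peptides + ddG labels from a declared rule
ds <- make_synthetic_ddg_dataset(n_proteins = 10, muts_per_protein = 30,
                                 seed = 3)

# pretrain the encoder on rotamer perturbations of three fixture peptides
set.seed(11)
peps <- list(make_peptide("GALSKYEWTNDQ", "alpha"),
             make_peptide("MKVLFRHCIPST", "extended"),
             make_peptide("ADEFGHIKLMNW", "alpha"))
samples <- make_perturbation_dataset(peps, per_structure = 50)
enc <- train_encoder(samples, encoder_config(head_dim = 8, epochs = 30,
                                             seed = 1))
tail(enc$history, 1)
#>    epoch train_loss val_loss
#> 31    30  0.9204278 1.583462

# featurize, train the 10-fold ensemble, evaluate held-out pairs
pl <- run_ddg_pipeline(ds$records, ds$structures, enc, seed = 5)
pl$report
#> EvalReport
#>  overall  n= 120  PCC  0.887  RMSE  0.65  MAE  0.54  ACC  0.87  MCC  0.735
#>  direct   n=  60  PCC  0.886  RMSE  0.65  MAE  0.55  ACC  0.90  MCC  0.794
#>  inverse  n=  60  PCC  0.890  RMSE  0.65  MAE  0.54  ACC  0.83  MCC  0.671
#>  snv      n=  23  PCC  0.740  RMSE  0.69  MAE  0.57  ACC  0.78  MCC  0.555
#>  non_snv  n=  37  PCC  0.933  RMSE  0.62  MAE  0.53  ACC  0.97  MCC  0.946
#>  bias     r_di -0.993  <delta>  0.009 kcal/mol
```

The training loss falls to ~0.22x its initial value (the encoder learns to
anticipate how far side-chain atoms move under rotamer perturbation), the
held-out correlation recovers the synthetic generative signal (60 held-out
direct/inverse pairs), and the paired predictions are nearly anti-symmetric
(r^{d-i} = -0.99, |⟨δ⟩| < 0.01 kcal/mol).

A command-line interface covers the same steps
(`inst/scripts/gatddg fixtures|pretrain|featurize|train|predict|evaluate`).

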