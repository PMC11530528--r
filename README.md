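# muse

Balanced multi-scale learning of biomolecular interactions by variational
expectation–maximization.

## What problem this solves, and for whom

Predicting labeled interactions between biomolecules — protein–protein
interaction types, drug–target binding, drug–drug effects — can draw on two
scales of information: each molecule's own *atomic structure* (a residue
contact graph from C-alpha coordinates, or an atom/bond graph from SMILES)
and the *molecular network* the molecules form. Models that fuse the two
naively tend to be greedy: the faster-learning scale dominates the shared
objective and the other is under-used.

`muse` is for computational biologists who want a desk-scale, fully
offline-testable implementation of the alternating solution: treat the
unobserved interaction labels `Y_LU` as latent variables and maximize the
evidence lower bound of the observed-label likelihood

```
log p_theta(Y_LV | G, A)  >=  E_{q_phi(Y_LU | G, D)} [ log p_theta(Y_LV, Y_LU | G, A) - log q_phi(Y_LU | G, D) ]
```

by alternating an **E-step** — a structure-scale GNN `q_phi` (GCN / GIN /
geometric message passing + symmetric pair classifier) fitted to observed
labels plus the network model's pseudo-labels — with an **M-step** — a
network-scale GIN `p_theta` with common-neighbor (NCN) pair scoring over a
*pseudo-edge-completed* adjacency (candidate pairs whose predicted existence
probability exceeds `1 - t` are added), fitted to observed labels plus the
E-step's pseudo-labels. Distillation weights `alpha` and `beta` balance the
supervised and mutual-supervision terms. A *utilization rate* diagnostic,
`u = (f(M) - f(M_single)) / f(M_single)` with `M_single` obtained by
feature-mean ablation of one scale, quantifies how much each scale actually
contributes.

## Worked example

```r
library(muse)

spec  <- synthetic_spec(n_entities = 120, n_links = 550, seed = 42)
data  <- generate_multiscale_network(spec)
print(data$network)
#> <interaction_network: 120 entities, 544 links (381 observed, 163 unobserved, 0 pseudo), multilabel C=3>

cfg   <- muse_config(seed = 1, epochs_per_step = 40, max_em_iterations = 4)
state <- run_em(data, cfg)
print(state)
#> <em_state [em]: 4 iteration(s), validation history: 0.733 0.758 0.810 0.860 0.826>

test <- which(data$network$links$status == "unobserved")
y    <- data$truth$labels[test, , drop = FALSE]
print(metrics_report(state$predictions, y))
#> Best-F1: 0.7059  AUROC: 0.7546  AUPRC: 0.7079
print(estimate_utilization(state, y))
#> u(structure)=0.194  u(network)=0.018  ratio=0.09  [f(M)=0.706 f(M0)=0.693 f(M1)=0.591]
```

Reading the output: the generator hid 30% of the 544 links; the validation
history starts at the prevalence baseline (0.733) and the run returns the
best iteration (0.860). On the hidden links the network-scale model reaches
Best-F1 0.706 (threshold-swept micro-F1). The utilization report compares
the full model `f(M)` with each scale ablated by feature-mean substitution:
removing the structure scale costs more (`f(M1) = 0.591`) than removing the
network scale (`f(M0) = 0.693`) on this small world, giving structure and
network utilization rates of 0.194 and 0.018.

## Command line

```sh
muse=$(Rscript -e 'cat(system.file("exec", "muse", package = "muse"))')
Rscript $muse simulate --spec spec.yaml --out data/
Rscript $muse train --config cfg.yaml --interactions data/interactions.tsv \
        --graphs data/graphs --out run/ --mode em --classes type1,type2,type3
Rscript $muse evaluate --run run/ --test held_out.tsv --classes type1,type2,type3
Rscript $muse analyze-balance --run run/ --test held_out.tsv --classes type1,type2,type3
```

Modes: `em` (the full framework), `joint` (the fused single-objective
baseline), `structure_only`, `network_only`. Configuration is one flat YAML
map (`em.alpha`, `em.beta`, `em.pseudo_threshold_t`, `encoder.hidden`,
`network.blocks`, ..., see `?read_config_file`); every run directory gets a
manifest with config snapshot and input digests.

## Package tour

| Area | Functions |
|---|---|
| Graph I/O | `read_interaction_table`, `parse_structure_chain`, `build_contact_graph`, `build_knn_graph`, `featurize_residues`, `molecular_graph_from_line_notation`, `read_graph_interchange` |
| Structure scale (E-step) | `structure_encoder_params`, `encode_structure_gcn`, `encode_structure_geometric`, `encode_drug_gin`, `readout`, `predict_pair_q`, `estep_loss`, `train_estep` |
| Network scale (M-step) | `network_model_params`, `gin_network_layer`, `common_neighbors`, `ncn_predict`, `augment_with_pseudo_edges`, `mstep_loss`, `train_mstep` |
| EM driver | `muse_config`, `run_em`, `run_joint_baseline`, `train_structure_only`, `train_network_only`, `check_convergence`, `estimate_utilization` |
| Synthetic data | `synthetic_spec`, `synthetic_spec_imbalance`, `generate_multiscale_network`, `split_links`, `sample_negative_pairs` |
| Evaluation | `best_f1`, `auroc`, `auprc`, `precision_recall_at_k`, `label_interchain_contacts`, `utilization_rate`, `utilization_ratio`, `metrics_report` |
| CLI | `muse_cli`, `cmd_simulate`, `cmd_train`, `cmd_evaluate`, `cmd_analyze_balance` |

The methods vignette (`vignettes/multiscale-em.Rmd`) documents the model,
the synthetic world and its limits, and every numerical choice.
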