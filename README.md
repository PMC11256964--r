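# domseg

Protein domain segmentation from 3D structure, for structural
bioinformaticians who need to chop experimental or predicted models into
domains at scale — e.g. to feed structure-comparison tools, build domain
libraries, or annotate predicted proteomes.

## The method

Domain assignments of a chain of length *L* are represented as a binary
co-membership matrix *A* = *V Vᵀ* (*a\_ij* = 1 iff residues *i* and *j*
share a domain; *V* is the one-hot *L* × *K* assignment matrix, with
all-zero rows for residues in no domain). Segmentation runs in two stages:

1. **Prediction.** A fully convolutional dilated residual network (3×3
   convolutions, instance norm, ELU, additive skips, dilations cycling
   1-2-4-8-16; 31 blocks × 32 filters at full scale) maps five *L* × *L*
   input channels — the Cα distance matrix plus helix/strand co-membership
   and boundary channels — to a symmetric soft adjacency *Â* of pairwise
   same-domain probabilities. Trained by binary cross-entropy against *A*;
   symmetry is enforced by adding the final logit map to its transpose.
2. **Decoding.** A greedy maximum-likelihood search finds the assignment
   maximizing the independent-Bernoulli log-likelihood
   ∑*ᵢ<ⱼ* [*a\_ij* log *â\_ij* + (1−*a\_ij*) log(1−*â\_ij*)], sweeping
   residues in sequence order, appending overflow domains as needed, and
   leaving unconvincing residues unassigned. A per-chain confidence
   exp(log-likelihood / *L*) scores the result, and a brute-force
   enumeration oracle validates the search at small *L*.

The package also provides CATH-style chopping-string I/O
(`"1-100,101-150_201-250"`), segmentation metrics (IoU under optimal
domain matching, correct-domain fraction at IoU ≥ 0.8, a tolerance-sweep
boundary distance score), and a synthetic-structure generator with known
domain labels, so the whole pipeline trains and validates without any
external dataset. The conv-net forward/backward passes are implemented in
C++ (im2col + GEMM) with Adam, inside the package.

## Worked example

Train a compact model on synthetic chains and segment a structure file:

```r
library(domseg)

# 120 synthetic chains (half single-domain, half 2-3 domains, sizes 20-40)
dataset <- make_dataset(120, seed = 1)
model <- train_segmenter(NULL, dataset,
                         training_config(epochs = 6, seed = 2),
                         network_config(n_blocks = 8, n_filters = 16))
summary(model)
#> <domain_cnn> 8 residual blocks, 16 filters, trained (38,417 parameters)
#> dilation cycle: 1,2,4,8,16; kernel 3; dropout 0.00
#> training: 720 steps over 6 epochs; mean BCE 0.3435 -> 0.0284

# a fresh two-domain chain, written to PDB and read back
g <- generate_chain(synthetic_spec(n_domains = 2, domain_sizes = c(35, 30)),
                    seed = 9)
write_structure(g$chain, "toy.pdb")
chain <- read_structure("toy.pdb")
seg <- predict(model, chain)
seg
#> <domain_segmentation> 2 domain(s), confidence 0.698
#> chopping: 1-33,41-70

# compare against the generating truth
format_chopping(g$assignment, g$chain)
#> [1] "1-35,41-70"
iou_score(seg$assignment, g$assignment)$iou
#> [1] 0.9714286
```

Reading the output: the mean binary cross-entropy falls from the
ln 2 ≈ 0.693 chance baseline toward zero as the network learns that
co-membership tracks contact density. The chopping string reports each
domain as author-numbered residue ranges (`_` joins the segments of a
discontinuous domain; residues assigned to no domain are omitted, which
is why the linker between the two domains appears in neither range). Here
both domains are found with the first boundary placed two residues early —
IoU 0.971 against the generating truth. The confidence is the
geometric-mean per-residue likelihood of the final assignment under the
predicted soft adjacency: it is near 1 only when the discrete assignment
reproduces the network's (saturated) prediction exactly, and a small
boundary disagreement — as here — pulls it down noticeably, which is
precisely what makes it a useful flag for boundary ambiguity. Across
chains it correlates positively with accuracy (rank correlation ≈ 0.7 on
held-out synthetic chains).

A command-line wrapper covers batch use:

```sh
DOMSEG=$(Rscript -e 'cat(system.file("scripts", "domseg.R", package = "domseg"))')
Rscript $DOMSEG train --synthetic 200 --epochs 10 --seed 1 --out model.rds
Rscript $DOMSEG predict --structure-dir structures/ --model model.rds --output pred.tsv
Rscript $DOMSEG evaluate --pred pred.tsv --truth reference.tsv
```

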