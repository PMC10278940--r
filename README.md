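# mtmap — multi-tissue transcriptome mapping

`mtmap` predicts an individual's gene expression profile in any target
tissue from any available source-tissue profile — typically whole blood,
the accessible "surrogate" sample — using a single multi-task conditional
encoder–generator model. Its audience is computational biologists who have
a multi-tissue reference cohort (samples × genes TPM tables plus a
sample → individual/tissue map) and want individualized cross-tissue
imputation together with the downstream analyses that make such predictions
credible: sample-wise and gene-wise accuracy, predictable-gene (pGene)
counting, latent-code individuality, tissue-similarity structure,
trait-association preservation and differential-expression concordance.

## The model

A unified encoder *E* embeds the standardized expression profile x of any
tissue *s* into a shared latent space, c = E(x | s); a generator *G*,
symmetric to the encoder, decodes a latent code into any target tissue's
expression space, G(c | t). Both are stacks of tissue-conditioning blocks —
a shared dense layer, a per-tissue learnable instance-level affine
(γ_t, β_t), and a leaky ReLU — so almost all parameters are shared across
tissues and scarce tissues borrow strength from data-rich ones. Two
auxiliary networks complete the objective: a discriminator *D* scored with
the hinge adversarial loss, and a mapping network *M* that turns Gaussian
noise z into latent codes c̃ = M(z) to smooth the latent space. Training
minimizes

    L = L_adv + λ_R · E‖E(G(c̃|t)|t) − c̃‖₁          (latent reconstruction)
              + λ_I · E‖G(E(x_s|s)|t) − x_t‖₁        (individualized prediction)
              + λ_C · E‖G(E(G(E(x_s|s)|t)|t)|s) − x_s‖₁   (cycle consistency)

over ordered within-individual tissue pairs (x_s, x_t), with the
discriminator trained on max(0, 1 − D(x|t)) + max(0, 1 + D(G(c̃|t)|t)).

A synthetic multi-tissue cohort simulator (shared per-individual latent
factors, tissue loading matrices with controllable cross-tissue sharing,
planted trait-linked and case/control-dysregulated genes, missingness) is a
first-class module, so the whole pipeline runs self-contained.

## Worked example

```r
library(mtmap)

# a synthetic cohort: 60 individuals, blood + 3 target tissues
cohort <- simulateCohort(simulationConfig(
  nIndividuals = 60, nTissues = 4, nGenes = 200, noiseSd = 0.6,
  loadingCor = 0.8, seed = 1))
cohort
#> MTMDataSet: 200 genes x 240 samples
#>   individuals: 60  tissues: 4
#>   simulation ground truth attached

split <- splitByIndividual(cohort, 0.8, seed = 1)
fit <- trainMTM(cohort, split$train, split$validation,
                config = trainConfig(batchSize = 32, maxEpochs = 40,
                                     learningRate = 1e-3, adamBeta1 = 0.9,
                                     adamBeta2 = 0.999, seed = 1),
                hidden = c(128, 64), latentDim = 32, noiseDim = 16,
                mapperHidden = 32)

# predict held-out individuals' tissue2 profiles from their blood samples
meta <- sampleInfo(cohort)
src <- meta[meta$tissue == "blood" & meta$individual_id %in% split$validation, ]
pred <- predictTissue(fit$lastModel, exprMatrix(cohort)[src$sample_id, ],
                      "tissue2", tissue = "blood", destandardize = FALSE)
obs <- applyScalers(cohort, fit$scalers)[sub("blood", "tissue2", src$sample_id), ]
rownames(pred) <- rownames(obs)
report <- evaluatePredictions(pred, obs, rep("tissue2", nrow(pred)))
report
#> EvaluationReport [model]
#>   sample-wise rho: mean 0.501 (n=12)
#>   gene-wise rho:   mean 0.488 (n=200)
#>   pGenes (rho > 0.3 ): tissue2=155
```

The sample-wise mean (0.501) is the average Pearson correlation between a
held-out individual's predicted and observed standardized tissue2 profile
across the 200 genes — how well individual deviations from the tissue mean
are reproduced per person. The gene-wise mean (0.488) averages, over genes,
the correlation between predicted and observed expression across the 12
held-out individuals; 155 of 200 genes exceed the pGene threshold
(gene-wise rho > 0.3), i.e. are individually predictable from blood in this
low-noise cohort.

Downstream, `latentCodeSimilarity(fit$lastModel, cohort)` contrasts
same-individual vs different-individual latent codes,
`tissueSimilarity`/`decodingPathSimilarity` compare generator internals to
the cohort's tissue-similarity structure, and `deAnalysis` + `concordance`
quantify how well case/control dysregulation survives prediction.

## Command-line interface

A thin wrapper is installed at `inst/scripts/mtm`:

```sh
mtm simulate --out cohort_dir --seed 1 --individuals 60 --tissues 4
mtm train    --expr expr.tsv --meta meta.tsv --out ckpt.rds --epochs 200
mtm predict  --model ckpt.rds --expr blood.tsv --meta meta.tsv \
             --target-tissue tissue2 --out pred.tsv
mtm evaluate --pred pred.tsv --obs obs.tsv --meta meta.tsv --out report/
```
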