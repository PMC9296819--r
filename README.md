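# metadecode

Meta-learned sample reweighting for neural decoding with noisy labels.

## The problem

Decoders that predict a behavioural variable (a trial type, a brain state)
from neural-activity features need large annotated training sets, but manual
annotation is noisy: a third or more of the training labels can be wrong,
and a deep decoder trained naively on such data generalizes poorly. Usually
a *small* set of trials can be annotated carefully. `metadecode` trains a
multilayer-perceptron decoder that uses such a small, clean validation set
to learn, online, how much to trust every training sample.

At each optimisation step the per-sample weights of the current mini-batch
are obtained by a meta-gradient: perturb the batch loss to
`sum_i eps_i * f_i(theta)`, take one inner gradient-descent step of size
`alpha`, and differentiate the mean validation loss through it at `eps = 0`,

    mu_i = eta * alpha * < grad mean-val-loss(theta), grad f_i(theta) >,

then rectify (`max(mu, 0)`) and normalize the weights to sum to one (a
guard returns all-zero weights when every `mu_i <= 0`), and update the
decoder with Adam on the weighted cross entropy. Training samples whose
gradients agree with the clean validation set are up-weighted; mislabeled
samples are driven to exactly zero weight.

The package also provides, as first-class tested components:

* a leaky integrate-and-fire population simulator (two groups of 40
  neurons, feed-forward wiring, additive current noise) whose binary label
  fires when `sin(pi * r_B) > 0.85` for the normalized mean group-B rate
  `r_B`, plus a calibration routine for the documented ~3:1 class ratio;
* annotator-style label noise by shuffling a portion of the labels, with
  mislabel masks and realised-noise bookkeeping;
* class-imbalance-aware evaluation (F1, balanced accuracy) and
  weight-separation statistics (zero-weight fractions, Wilcoxon rank-sum);
* experiment runners for the noise sweep, the validation-size sweep,
  pooled mixed-quality training sets, and session-structured
  trial-trajectory (calcium-imaging-style) decoding, with a synthetic
  multi-session fixture generator.

## A worked example

Simulate the study, shuffle every training label slot (portion parameter
100%, realised noise ~36%), and train with a 20-sample class-balanced
validation guide. Features are standardized with training-split statistics
(the documented preprocessing; the experiment runners do this themselves):

```r
library(metadecode)

params <- calibrate_simulator(simulator_params(), 0.23, seed = 1)
train <- shuffle_labels(generate_dataset(params, 600, seed = 105), 1.0,
                        seed = 205)
pool  <- shuffle_labels(generate_dataset(params, 600, seed = 301), 0.10,
                        seed = 302)
test  <- generate_dataset(params, 600, seed = 401)

realized_noise_level(train)
#> [1] 0.3566667

val <- subset_dataset(pool, withr::with_seed(7,
  c(sample(which(pool$labels == 0), 10), sample(which(pool$labels == 1), 10))))
sets <- standardize_features(train, val, test)

fit <- train_reweighted(sets[[1]], sets[[2]], trainer_config())
fit
#> Sample-reweighted MLP decoder (80-128-64-2)
#>   600 training / 20 validation samples, 51 epoch(s) run
#>   final weighted loss 0.3737, validation loss 0.1622

evaluate_model(fit, sets[[3]])
#> Evaluation: F1 = 0.928, balanced accuracy = 0.973 (n = 600)

weight_separation(fit$aggregate_weights, train$mislabel_mask)
#> Weight separation (386 correct vs 214 mislabeled)
#>   mean weight: correct 0.0534, mislabeled 0.0439
#>   mislabeled with weight exactly 0: 84.1%
#>   Wilcoxon rank-sum W = 65108, two-sided p = 8.43e-34
```

Although 36% of the training labels are wrong, the decoder reaches F1 0.93
and balanced accuracy 0.97 on the clean test set, and 84% of the mislabeled
samples receive *exactly* zero weight — the reweighting has effectively
removed them from the loss. Plain training on the same data (`baseline1`)
collapses toward all-majority predictions at this noise level.

`plot(fit, "loss")` draws the weighted-training and validation loss curves,
`plot(fit, "weights")` the weight boxplots by mislabel status, and
`summary(fit)` prints the separation statistics. The full studies are one
call each, e.g.

```r
plan <- experiment_plan(seed = 1)
study <- build_study_data(plan)      # calibrate + generate all datasets
run_noise_sweep(plan, study)         # 5 noise levels x 3 methods
```

A thin command-line wrapper for simulate/corrupt/train/evaluate lives in
`inst/scripts/metadecode-cli.R`.

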