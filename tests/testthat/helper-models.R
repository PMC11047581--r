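# Shared fixtures. Trained models are expensive, so each is built once
# per test run (lazily) and reused by every test that needs it. All
# fixture datasets come from the package's own CBF simulator; jitter is
# scaled to the 64-timestep desk size (variance 4 ~ sd 2 samples).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  got <- .fixtures[[key]]
  if (!is.null(got)) return(got)
  val <- fn()
  .fixtures[[key]] <- val
  val
}

cbf_one_class <- function() {
  memo("cbf1", function() {
    ss <- generate_simulated(sim_config(n_per_class = 288, length = 64,
                                        n_classes = 1, pattern_var = 4,
                                        seed = 7))
    list(train = subset_signals(ss, 1:256), held = subset_signals(ss, 257:288))
  })
}

cbf_three_class <- function() {
  memo("cbf3", function() {
    tr <- generate_simulated(sim_config(n_per_class = 100, length = 64,
                                        n_classes = 3, pattern_var = 4,
                                        seed = 11))
    te <- generate_simulated(sim_config(n_per_class = 50, length = 64,
                                        n_classes = 3, pattern_var = 4,
                                        seed = 12))
    list(train = tr, test = te)
  })
}

# Low-intrinsic-noise CBF for the restoration experiments: the added
# corruption must dominate the unrecoverable intrinsic noise for
# restoration MSE to be a meaningful target (see the methods vignette).
cbf_clean <- function() {
  memo("cbf_clean", function() {
    ss <- generate_simulated(sim_config(n_per_class = 320, length = 64,
                                        n_classes = 1, pattern_var = 4,
                                        noise_sd = 0.1, seed = 7))
    list(train = subset_signals(ss, 1:256), held = subset_signals(ss, 257:320))
  })
}

# Reference-scale unconditional model: 1 CBF class, n = 256, L = 64,
# T = 100 cosine, 3-level U-Net, at most 30 epochs with early stopping.
uncond_fit <- function() {
  memo("uncond_fit", function() {
    d <- cbf_one_class()
    train_diffusion(d$train,
                    train_config(T_steps = 100, schedule_kind = "cosine",
                                 max_epochs = 30, patience = 10,
                                 batch_size = 16, seed = 1),
                    mode = "uncond")
  })
}

uncond_generated <- function() {
  memo("uncond_gen", function() {
    sample_diffusion(uncond_fit(), 64, seed = 2, var_mode = "beta_tilde")
  })
}

# Label-conditional model on the balanced 3-class set. Class
# faithfulness converges more slowly than marginal fidelity, hence the
# longer epoch cap than the unconditional run.
label_fit <- function() {
  memo("label_fit", function() {
    d <- cbf_three_class()
    train_diffusion(d$train,
                    train_config(T_steps = 100, schedule_kind = "cosine",
                                 max_epochs = 40, patience = 12,
                                 batch_size = 16, seed = 1),
                    mode = "label")
  })
}

# The imbalance experiment's generator is trained on the imbalanced
# training set itself (the test set stays untouched).
imbalanced_train <- function() {
  memo("imb_train", function() {
    make_imbalanced(cbf_three_class()$train, c(1.0, 1.0, 0.05), seed = 2)
  })
}

imbalanced_label_fit <- function() {
  memo("imb_label_fit", function() {
    train_diffusion(imbalanced_train(),
                    train_config(T_steps = 100, schedule_kind = "cosine",
                                 max_epochs = 40, patience = 12,
                                 batch_size = 16, seed = 1),
                    mode = "label")
  })
}

# Signal-conditional models (thermal noise / masked gaps) on the
# low-noise set. Conditioning carries most of the information, so they
# converge in far fewer epochs than the unconditional model; the gap
# model's target (beat zero-fill) is much easier than the thermal
# model's and needs fewer still.
signal_fit <- function(kind) {
  memo(paste0("signal_fit_", kind), function() {
    d <- cbf_clean()
    degr <- if (kind == "thermal") {
      degradation_spec("thermal", magnitude = 0.3, seed = 1)
    } else {
      degradation_spec("mask_gaps", gap_fraction = 0.25, seed = 1)
    }
    train_diffusion(d$train,
                    train_config(T_steps = 100, schedule_kind = "cosine",
                                 max_epochs = if (kind == "thermal") 25 else 15,
                                 patience = 10, batch_size = 16, seed = 1),
                    mode = "signal", degradation = degr)
  })
}

white_noise_set <- function(n = 64, L = 64, seed = 41) {
  set.seed(seed)
  signal_set(array(stats::rnorm(n * L), c(n, 1L, L)))
}
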