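# Shared fixtures, all built in code.

# a TCRC set with arbitrary curve values on a common grid
make_set <- function(curve_values, nc_values, chemical_id = "chem",
                     label = NA_character_, t_start = 0) {
  n <- length(curve_values)
  len <- length(nc_values)
  tt <- seq(t_start, t_start + len - 1)
  concs <- 100 / 3^(seq_len(n) - 1)
  curves <- lapply(seq_len(n), function(i)
    tcrc(tt, curve_values[[i]], concs[i], chemical_id))
  tcrc_set(chemical_id, curves,
           tcrc(tt, nc_values, "negative_control", chemical_id),
           label = label, n_curves = n)
}

# a standard 73-sample noiseless set from the generator's first archetype
make_default_set <- function(chemical_id = "chem", label = "C1") {
  cfg <- preset_config("separable")
  generate_tcrc_set(cfg$archetypes[[1]], cfg, chemical_id = chemical_id,
                    label = label, noise = FALSE)
}

# two well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 20, sep = 6, seed = 11) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  list(x = x, labels = rep(c("A", "B"), each = n_per))
}

# XOR pattern: 4 cluster centers, alternating labels
make_xor <- function(n = 100, seed = 12) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 4, 4, 0, 4, 4, 0), ncol = 2, byrow = TRUE)
  cl <- rep(1:4, length.out = n)
  x <- centers[cl, ] + matrix(rnorm(2 * n, sd = 0.5), ncol = 2)
  list(x = x, labels = ifelse(cl <= 2, "A", "B"))
}

# classifier stub that memorizes the truth (oracle)
oracle_classifier <- function() {
  list(train = function(x, y) list(x = x, y = y),
       predict = function(model, x) {
         idx <- apply(x, 1, function(r)
           which.min(colSums((t(model$x) - r)^2)))
         model$y[idx]
       })
}

# classifier stub that always predicts the majority training class
majority_classifier <- function() {
  list(train = function(x, y) names(which.max(table(y))),
       predict = function(model, x) rep(model, nrow(x)))
}
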