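# Fixture builders shared across test files. Everything is generated in code;
# seeds are fixed so expectations are stable.

random_cloud <- function(n, seed = 1, scale = 10) {
  set.seed(seed)
  point_cloud(matrix(stats::rnorm(n * 3, sd = scale), n, 3))
}

# 10 points on the x axis at 0..9: the canonical FPS tie-break fixture
collinear_cloud <- function() point_cloud(cbind(0:9, 0, 0))

# dense Gaussian blob + sparse spherical shell, for entropy-FPS behaviour
blob_shell_cloud <- function(seed = 11, n_blob = 200, n_shell = 40,
                             shell_radius = 30) {
  set.seed(seed)
  blob <- matrix(stats::rnorm(n_blob * 3, sd = 2), n_blob, 3)
  dirs <- matrix(stats::rnorm(n_shell * 3), n_shell, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  point_cloud(rbind(blob, dirs * shell_radius))
}

# small well-separated phantom resampled to a fixed size for network tests
phantom_training_set <- function(n, m = 512L, seed0 = 100, noise_sd = 0,
                                 task = c("endplate", "pedicle")) {
  task <- match.arg(task)
  set.seed(seed0)
  thetas <- stats::runif(n, 0, 25)
  lapply(seq_len(n), function(i) {
    ph <- generate_vertebra(phantom_config(theta = thetas[i],
                                           noise_sd = noise_sd,
                                           seed = seed0 + i))
    lab <- if (task == "endplate") ph$endplate_task else ph$pedicle_task
    resample_to_size(lab, m = m, draws = 1L, seed = i, method = "fps")[[1]]
  })
}

# independent two-way mean squares via stats::aov, used as the ANOVA oracle
aov_mean_squares <- function(values) {
  df <- data.frame(y = as.numeric(values),
                   subj = factor(rep(seq_len(nrow(values)), ncol(values))),
                   rater = factor(rep(seq_len(ncol(values)),
                                      each = nrow(values))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  list(MSR = tab["subj", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"])
}
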