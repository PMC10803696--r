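# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

base_params <- function() memo("base_params", default_parameters())

default_patient <- function() {
  memo("default_patient", make_virtual_patient(base_params(), 20, 40))
}

full_model <- function(albumin = TRUE, kd_alb = NULL) {
  key <- paste0("full_", albumin, "_", kd_alb %||% "default")
  memo(key, {
    p <- base_params()
    if (!is.null(kd_alb)) p$K_D_alb <- kd_alb
    build_pbrpk_model(make_virtual_patient(p, 20, 40),
                      model_options(albumin_enabled = albumin))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent two-compartment oracle: matrix exponential of the hot-pair
# rate matrix (k12/k21 exchange plus decay loss from the hot states)
two_compartment_hot_oracle <- function(t, k12, k21, lambda, h0 = c(1, 0)) {
  A <- matrix(c(-(k12 + lambda), k21, k12, -(k21 + lambda)),
              2, 2, byrow = TRUE)
  as.numeric(Matrix::expm(A * t) %*% h0)
}

max_rel_err <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), .Machine$double.eps))
}
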