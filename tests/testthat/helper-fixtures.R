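# shared fixtures, built once per test run
fx <- new.env()

fx$params <- local_circuit_params()
fx$const <- compute_balance_constants(fx$params)

# canonical synthetic substrate used by the network-level tests
fx$bundle <- generate_synthetic_connectome(seed = 1)

fx_network <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(fx[[key]])) fx[[key]] <- build_network(fx$bundle, ...)
  fx[[key]]
}

# two-area toy bundle: reciprocal pair, feedforward A1 -> A2
toy_bundle <- function(n = 2, fln = 0.05) {
  FLN <- matrix(0, n, n)
  FLN[row(FLN) != col(FLN)] <- fln
  h <- seq(0, 1, length.out = n)
  SLN <- stats::plogis(4 * outer(h, h, "-"))
  diag(SLN) <- 0.5
  connectome_bundle(paste0("A", seq_len(n)), FLN, SLN,
                    hierarchy = stats::setNames(h, paste0("A", seq_len(n))))
}
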