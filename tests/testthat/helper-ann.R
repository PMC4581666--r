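mlp_loss <- function(model, X, T_mat) {
  mean((forward_mlp(model, X)$y - T_mat)^2)
}

# Recover the analytic gradient through the public API: one full-batch
# update with unit learning rate moves each parameter by exactly its
# gradient.
one_step_gradients <- function(X, T_mat, q, seed) {
  m0 <- withr::with_seed(seed, new_mlp(ncol(X), q, ncol(T_mat)))
  m1 <- train_backprop(X, T_mat, q = q, iterations = 1, learning_rate = 1,
                       seed = seed)
  list(model = m0,
       w_in = m0$w_in - m1$w_in,
       theta_hidden = m0$theta_hidden - m1$theta_hidden,
       w_out = m0$w_out - m1$w_out,
       theta_out = m0$theta_out - m1$theta_out)
}
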