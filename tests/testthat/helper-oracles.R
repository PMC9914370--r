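# Independent oracles, written against the published equations term by term,
# deliberately not sharing code with the package implementation.

# Per-term right-hand side: scalar arithmetic, one line per term of each
# equation, using the greek-lettered symbols' ASCII names directly.
oracle_rhs <- function(y, p, s, u) {
  Tu <- y[["Tu"]]; Ti <- y[["Ti"]]; V <- y[["V"]]; X <- y[["X"]]
  Y <- y[["Y"]]; C <- y[["C"]]; W <- y[["W"]]; Z <- y[["Z"]]; N <- y[["N"]]

  dTu <- p[["r_u"]] * Tu * (1 - (Tu + Ti) / p[["K_t"]])
  dTu <- dTu - p[["beta_t"]] * Tu * V / (p[["m_v"]] + Tu)
  dTu <- dTu - p[["delta_c"]] * Tu * C / (p[["m_t"]] + Tu)
  dTu <- dTu - p[["delta_x"]] * X * Tu / (p[["m_x"]] + X)
  dTu <- dTu - p[["d_u"]] * N * Tu

  dTi <- p[["r_i"]] * Ti * (1 - (Tu + Ti) / p[["K_t"]])
  dTi <- dTi + p[["beta_t"]] * Tu * V / (Tu + p[["m_v"]])
  dTi <- dTi - p[["a_t"]] * Ti
  dTi <- dTi - p[["delta_x"]] * X * Ti / (p[["m_x"]] + X)
  dTi <- dTi - p[["delta_c"]] * Ti * C / (p[["m_t"]] + Ti)
  dTi <- dTi - p[["delta_z"]] * Z * Ti
  dTi <- dTi - p[["d_i"]] * N * Ti

  dV <- p[["b_t"]] * p[["a_t"]] * Ti
  dV <- dV - p[["delta_v"]] * V * Z
  dV <- dV - p[["gamma_v"]] * V
  dV <- dV - p[["d_v"]] * N * V
  dV <- dV + s

  dX <- p[["a_v"]] * N * V
  dX <- dX + p[["a_x"]] * (Ti + Tu) / (p[["h_x"]] + Ti + Tu)
  dX <- dX - p[["gamma_x"]] * X

  dY <- p[["a_v"]] * N * V / (1 + p[["nu"]] * W)
  dY <- dY + p[["a_y"]] * (Ti + Tu) /
    ((p[["h_y"]] + Ti + Tu) * (1 + p[["nu"]] * W)) * C
  dY <- dY - p[["gamma_y"]] * Y

  dC <- p[["alpha_n"]] * (Ti + Tu) / (1 + p[["b_n"]] * W) * N
  dC <- dC + p[["alpha_x"]] * (Ti + Tu) / (1 + p[["b_x"]] * W) * X
  dC <- dC + p[["alpha_y"]] * (Ti + Tu) / (1 + p[["b_y"]] * W) * Y
  dC <- dC - p[["gamma_c"]] * C

  dW <- p[["r_x"]] * (1 - u) * X + p[["r_y"]] * (1 - u) * Y -
    p[["gamma_w"]] * W

  dZ <- p[["p_v"]] * Ti - p[["gamma_z"]] * Z

  dN <- p[["s_n"]]
  dN <- dN + p[["r_n"]] * N * (1 - N / p[["K_n"]]) * (Ti / (Ti + p[["m_n"]]))
  dN <- dN + p[["zeta"]] * C * N / (C + p[["h_n"]])
  dN <- dN - p[["delta_n"]] * (Tu + Ti) * N
  dN <- dN - p[["gamma_n"]] * N

  c(Tu = dTu, Ti = dTi, V = dV, X = dX, Y = dY, C = dC, W = dW, Z = dZ,
    N = dN)
}

# Partial correlation on ranks via inversion of the joint correlation matrix:
# prc_j = -P[j, y] / sqrt(P[j, j] * P[y, y]) with P = solve(cor(ranks)).
oracle_prcc <- function(X, y) {
  R <- cbind(apply(X, 2, rank, ties.method = "average"),
             .y = rank(y, ties.method = "average"))
  P <- solve(stats::cor(R))
  k <- ncol(R)
  co <- vapply(seq_len(k - 1), function(j)
    -P[j, k] / sqrt(P[j, j] * P[k, k]), numeric(1))
  stats::setNames(co, colnames(X))
}

# Random positive state/parameter draws around baseline for property tests.
random_state <- function() {
  s <- ovt_init()
  vals <- abs(c(runif(1, 0, 3.3e9), runif(1, 0, 1e8), runif(1, 0, 1e9),
                runif(1, 0, 1e5), runif(1, 0, 1e5), runif(1, 0, 1e7),
                runif(1, 0, 1e7), runif(1, 0, 1e5), runif(1, 0, 1e6)))
  stats::setNames(vals, names(s))
}

random_params <- function() {
  p <- ovt_params()
  scale <- exp(runif(length(p), log(0.5), log(2)))
  ovt_params(overrides = stats::setNames(as.list(as.numeric(p) * scale),
                                         names(p)))
}
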