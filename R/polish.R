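## Exact LP refinement of a stage solution by proximal-point iteration with
## quadprog: repeatedly solve
##     min  c'v + (rho/2) ||v - ref||^2   s.t.  M v <= b, v >= 0
## The proximal-point method on a linear program converges finitely, so a few
## iterations started from the first-order (PDHG) solution recover the exact
## stage optimum on desk-scale problems. Used by the accurate solver profile;
## the first-order path remains the scalable default.

# Assemble the stage LP in (x, aux) variables from the block description
# (same encoding as cpp_pdhg_stage) and polish x_init.
.polish_stage <- function(A_full, map, d0, kind, r0, r1, wgt, thr, bnd,
                          x_init, rho = 1e-4, iters = 30, max_dim = 2000) {
  n <- ncol(A_full)
  nb <- length(kind)
  # pass 1: sizes
  n_aux <- 0L
  for (b in seq_len(nb)) {
    if (kind[b] %in% c(1L, 2L, 5L, 6L)) n_aux <- n_aux + (r1[b] - r0[b] + 1L)
  }
  nvar <- n + n_aux
  if (nvar > max_dim) return(NULL)

  cvec <- numeric(nvar)
  Mi <- list(); bvec_list <- list()
  aux_off <- n
  con <- list() # each: list(rows = sparse row matrix over nvar, rhs)
  add_con <- function(Mrow, rhs) {
    con[[length(con) + 1L]] <<- list(M = Mrow, rhs = rhs)
  }
  for (b in seq_len(nb)) {
    k <- kind[b]
    if (k == 7L) next
    rs <- r0[b]:r1[b]
    br <- map[rs] # 1-based base rows
    o <- d0[rs]
    mb <- length(rs)
    Ab <- A_full[br, , drop = FALSE]
    w <- wgt[b]; t <- thr[b]; B <- bnd[b]
    if (k == 0L) {
      cvec[1:n] <- cvec[1:n] + w * Matrix::colSums(Ab)
    } else if (k == 1L || k == 2L) {
      ai <- aux_off + seq_len(mb); aux_off <- aux_off + mb
      cvec[ai] <- w
      E <- Matrix::sparseMatrix(i = seq_len(mb), j = ai, x = 1,
                                dims = c(mb, nvar))
      Ax <- methods::as(Matrix::sparseMatrix(i = integer(), j = integer(),
                                             x = numeric(), dims = c(mb, nvar)),
                        "CsparseMatrix")
      Ax[, 1:n] <- Ab
      if (k == 1L) add_con(-(Ax + E), -(t - o)) # A x + u >= t - o
      else add_con(Ax - E, t - o)               # A x - s <= t - o
    } else if (k == 3L) {
      Ax <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(mb, nvar))
      Ax[, 1:n] <- Ab
      add_con(Ax, B - o)
    } else if (k == 4L) {
      a <- w * Matrix::colSums(Ab)
      Mrow <- Matrix::sparseMatrix(i = rep(1L, n), j = 1:n, x = a,
                                   dims = c(1L, nvar))
      add_con(Mrow, B - w * sum(o))
    } else if (k == 5L || k == 6L) {
      ai <- aux_off + seq_len(mb); aux_off <- aux_off + mb
      E <- Matrix::sparseMatrix(i = seq_len(mb), j = ai, x = 1,
                                dims = c(mb, nvar))
      Ax <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(mb, nvar))
      Ax[, 1:n] <- Ab
      if (k == 5L) add_con(-(Ax + E), -(t - o)) else add_con(Ax - E, t - o)
      Srow <- Matrix::sparseMatrix(i = rep(1L, mb), j = ai, x = rep(w, mb),
                                   dims = c(1L, nvar))
      add_con(Srow, B)
    } else if (k == 8L) {
      Ax <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(mb, nvar))
      Ax[, 1:n] <- Ab
      add_con(-Ax, -(t - o))
    } else if (k == 9L) {
      Ax <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(mb, nvar))
      Ax[, 1:n] <- Ab
      add_con(Ax, t - o)
    }
  }
  M <- do.call(rbind, lapply(con, `[[`, "M"))
  bv <- unlist(lapply(con, `[[`, "rhs"), use.names = FALSE)
  ncon <- nrow(M)

  # initial aux values implied by x_init
  v <- numeric(nvar)
  v[1:n] <- x_init
  aux_off2 <- n
  base_dose <- as.numeric(A_full %*% x_init)
  for (b in seq_len(nb)) {
    k <- kind[b]
    if (!(k %in% c(1L, 2L, 5L, 6L))) next
    rs <- r0[b]:r1[b]
    d <- base_dose[map[rs]] + d0[rs]
    mb <- length(rs)
    ai <- aux_off2 + seq_len(mb); aux_off2 <- aux_off2 + mb
    v[ai] <- if (k %in% c(1L, 5L)) pmax(thr[b] - d, 0) else pmax(d - thr[b], 0)
  }

  # quadprog wants  Amat' v >= bvec  with PD Dmat
  Mneg <- methods::as(-M, "CsparseMatrix")
  Eye <- methods::as(Matrix::Diagonal(nvar), "CsparseMatrix")
  Amat <- as.matrix(Matrix::t(Matrix::rbind2(Mneg, Eye)))
  bqp <- c(-bv, numeric(nvar))
  sc <- max(abs(cvec), 1e-8)
  rho_eff <- rho * sc
  prev <- v
  done <- 0L
  for (it in seq_len(iters)) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = diag(rho_eff, nvar),
                         dvec = rho_eff * prev - cvec,
                         Amat = Amat, bvec = bqp, meq = 0),
      error = function(e) NULL)
    if (is.null(sol)) {
      # proximal weight too small for the active-set solver: back off
      rho_eff <- rho_eff * 50
      if (rho_eff > 1e3 * sc) return(if (done > 0L) prev[1:n] else NULL)
      next
    }
    done <- done + 1L
    vnew <- sol$solution
    if (sqrt(sum((vnew - prev)^2)) <= 1e-9 * (1 + sqrt(sum(prev^2)))) {
      prev <- vnew; break
    }
    prev <- vnew
  }
  if (done == 0L) return(NULL)
  pmax(prev[1:n], 0)
}
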