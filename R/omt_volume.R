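## Cubic volume-measure-preserving OMT map by homotopy continuation.
##
## The boundary is swept from the identity to the cubic boundary map along a
## uniform partition of [0,1]; at each step the interior is the solution of
## a Dirichlet problem for the mass-weighted Laplacian assembled from the
## previous iterate.

#' Homotopy of the boundary map
#'
#' \eqn{g_\zeta(\hat v) = (1-\zeta)\hat v + \zeta g^*_\rho(\hat v)}.
#'
#' @param mesh a \linkS4class{TetMesh} (normalized).
#' @param gstar boundary \linkS4class{PLMap} onto the cube boundary.
#' @param zeta homotopy parameter in \eqn{[0,1]}.
#' @return a \linkS4class{PLMap} on the boundary vertices.
#' @export
homotopyBoundary <- function(mesh, gstar, zeta) {
  if (length(zeta) != 1L || is.na(zeta) || zeta < 0 || zeta > 1)
    stop("zeta must lie in [0, 1]")
  vb <- mesh@vertices[gstar@vertexIds, , drop = FALSE]
  new("PLMap", coords = (1 - zeta) * vb + zeta * gstar@coords,
      vertexIds = gstar@vertexIds,
      target = if (zeta == 1) "cubeBoundary" else "free")
}

#' Mass-weighted Laplacian of a volumetric map
#'
#' Off-diagonal entries follow
#' \eqn{w_{ij}(f) = -\frac{1}{9} \sum_\tau
#' |f([v_i,v_\ell,v_m])|\,|f([v_j,v_m,v_\ell])|\cos\theta^{\ell,m}_{ij}(f) /
#' (\rho(\tau)|\tau|)} summed over tetrahedra containing the opposite edge
#' pair; the diagonal is the negative row sum. The summand is evaluated
#' through the identity
#' \eqn{|A_i||A_j|\cos\theta = -\tfrac14\, n_i\cdot n_j}
#' with \eqn{n_k} the outward area vectors of the image faces.
#'
#' @param f image coordinates (n x 3 matrix or \linkS4class{PLMap} over all
#'   vertices).
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @param tetMass optional precomputed \eqn{\rho(\tau)|\tau|} (from
#'   [simplexMeasures()]), saving recomputation across homotopy steps.
#' @return sparse symmetric \code{dgCMatrix} (zero row sums).
#' @export
massLaplacian <- function(f, mesh, rho, tetMass = NULL) {
  if (is(f, "PLMap")) f <- f@coords
  tets <- mesh@tets
  denom <- if (is.null(tetMass)) simplexMeasures(mesh, rho)$tetMass
           else tetMass
  if (any(denom <= 0)) stop("rho(tau)|tau| must be positive for every tet")
  ## outward area vectors of the image faces opposite each vertex
  P <- lapply(1:4, function(k) f[tets[, k], , drop = FALSE])
  nrm <- list(rowCross(P[[3]] - P[[2]], P[[4]] - P[[2]]),
              rowCross(P[[4]] - P[[1]], P[[3]] - P[[1]]),
              rowCross(P[[2]] - P[[1]], P[[4]] - P[[1]]),
              rowCross(P[[3]] - P[[1]], P[[2]] - P[[1]]))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ii <- jj <- ww <- vector("list", 6)
  for (e in 1:6) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ii[[e]] <- tets[, i]
    jj[[e]] <- tets[, j]
    ww[[e]] <- rowSums(nrm[[i]] * nrm[[j]]) / (36 * denom)
  }
  ii <- unlist(ii); jj <- unlist(jj); ww <- unlist(ww)
  n <- nVertices(mesh)
  L <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                    dims = c(n, n))
  L - Diagonal(n, Matrix::rowSums(L))
}

#' Transport cost of a volumetric map
#'
#' \eqn{c_\rho(f) = \sum_v \lVert v - f(v)\rVert_2^2\, m_\rho(v)}.
#'
#' @param f image coordinates (n x 3 matrix or \linkS4class{PLMap}).
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @return non-negative scalar.
#' @export
transportCost <- function(f, mesh, rho) {
  if (is(f, "PLMap")) f <- f@coords
  meas <- simplexMeasures(mesh, rho)
  sum(rowSums((mesh@vertices - f)^2) * meas$vertexVolumeMeasure)
}

#' Transport cost of a boundary map
#'
#' \eqn{d_\rho(g) = \sum_{\hat v} \lVert \hat v - g(\hat v)\rVert_2^2\,
#' a_\rho(\hat v)}.
#'
#' @param g boundary \linkS4class{PLMap}.
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @return non-negative scalar.
#' @export
boundaryCost <- function(g, mesh, rho) {
  meas <- simplexMeasures(mesh, rho)
  vb <- mesh@vertices[g@vertexIds, , drop = FALSE]
  sum(rowSums((vb - g@coords)^2) * meas$vertexAreaMeasure[g@vertexIds])
}

#' Mass-distortion diagnostics of a volumetric map
#'
#' Total mass distortion
#' \eqn{d_{\mathcal M}(f) = \sum_v \sum_{\tau\in\mathcal N(v)}
#' |\rho(\tau)|\tau| - |f(\tau)||/4} and the local mass ratio
#' \eqn{r_f(v)}, reported as the mean over the 1-ring
#' \eqn{\mathcal N(v)} of \eqn{\rho(\tau)|\tau|/|f(\tau)|} (the raw 1-ring
#' sum is kept in \code{localRatioSum}). Image tetrahedra with non-positive
#' signed volume are counted as folded; collapsed image tets give
#' non-finite ratios, which are excluded from the reported median with
#' their count.
#'
#' @param f image coordinates (n x 3 matrix or \linkS4class{PLMap}).
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @return list with \code{massDistortion}, \code{localRatio} (per-vertex
#'   mean), \code{localRatioSum}, \code{localDistortion} (per-vertex),
#'   \code{medianRatio}, \code{foldingCount}, \code{imageVolume},
#'   \code{nonFiniteRatios}.
#' @export
distortionDiagnostics <- function(f, mesh, rho) {
  if (is(f, "PLMap")) f <- f@coords
  meas <- simplexMeasures(mesh, rho)
  fvolSigned <- tetVolumes(f, mesh@tets)
  fvol <- abs(fvolSigned)
  tetDist <- abs(meas$tetMass - fvol)
  ratio <- meas$tetMass / fvol
  n <- nVertices(mesh)
  deg <- ringSum <- ringDist <- numeric(n)
  for (k in 1:4) {
    acc <- rowsum(cbind(1, ratio, tetDist), mesh@tets[, k])
    ids <- as.integer(rownames(acc))
    deg[ids] <- deg[ids] + acc[, 1]
    ringSum[ids] <- ringSum[ids] + acc[, 2]
    ringDist[ids] <- ringDist[ids] + acc[, 3]
  }
  localRatio <- ringSum / deg
  finite <- is.finite(localRatio)
  list(massDistortion = sum(ringDist) / 4,
       localRatio = localRatio,
       localRatioSum = ringSum,
       localDistortion = ringDist / 4,
       medianRatio = median(localRatio[finite]),
       foldingCount = sum(fvolSigned <= 0),
       imageVolume = sum(fvol),
       nonFiniteRatios = sum(!finite))
}

#' Cubic volume-measure-preserving OMT map (homotopy continuation)
#'
#' Starting from the identity, the boundary is pinned to
#' \eqn{g_{\zeta_k}} over a uniform partition
#' \eqn{0=\zeta_0<\cdots<\zeta_p=1} and the interior solves
#' \eqn{[L_V(f^{(k-1)})]_{II} f^{(k)}_I = -[L_V(f^{(k-1)})]_{IB}\,
#' g_{\zeta_k}} at each step. The final iterate \eqn{f^{(p)}} maps the mesh
#' onto the unit cube.
#'
#' @param mesh normalized \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @param gstar boundary \linkS4class{PLMap} onto the cube boundary (from
#'   [cubeBoundaryAOMT()]).
#' @param p number of homotopy partitions (default 11).
#' @param residTol relative residual bound for each interior solve.
#' @return list with \code{map} (a \linkS4class{PLMap} onto the cube) and
#'   \code{diagnostics}: per-step transport cost, mass distortion, folding,
#'   plus the final [distortionDiagnostics()] report.
#' @export
volumeOMT <- function(mesh, rho, gstar, p = 11L, residTol = 1e-8) {
  if (p < 1) stop("p must be at least 1")
  n <- nVertices(mesh)
  B <- gstar@vertexIds
  I <- setdiff(seq_len(n), B)
  if (!setequal(B, mesh@boundaryVertexIds))
    stop("gstar must be defined on the mesh boundary vertices")
  f <- mesh@vertices
  vb <- mesh@vertices[B, , drop = FALSE]
  meas <- simplexMeasures(mesh, rho)
  trace <- vector("list", p)
  for (k in seq_len(p)) {
    zeta <- k / p
    gb <- (1 - zeta) * vb + zeta * gstar@coords
    L <- massLaplacian(f, mesh, rho, tetMass = meas$tetMass)
    LII <- L[I, I, drop = FALSE]
    LIB <- L[I, B, drop = FALSE]
    rhs <- -as.matrix(LIB %*% gb)
    ## supernodal sparse Cholesky (the interior operator is SPD for
    ## nondegenerate iterates); sparse LU as fallback
    fI <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(LII), LDL = FALSE,
                             super = TRUE, perm = TRUE)
      as.matrix(Matrix::solve(ch, rhs))
    }, error = function(e) tryCatch(as.matrix(Matrix::solve(LII, rhs)),
      error = function(e2)
        stop("singular interior system at homotopy step ", k, ": ",
             conditionMessage(e2))))
    resid <- norm(as.matrix(LII %*% fI) - rhs, "F") / max(norm(rhs, "F"),
                                                          .Machine$double.eps)
    if (!is.finite(resid) || resid > residTol)
      stop(sprintf("interior solve did not converge at step %d (relative residual %.3g)",
                   k, resid))
    f[I, ] <- fI
    f[B, ] <- gb
    fvol <- tetVolumes(f, mesh@tets)
    trace[[k]] <- list(zeta = zeta,
                       transportCost = sum(rowSums((mesh@vertices - f)^2) *
                                             meas$vertexVolumeMeasure),
                       massDistortion = sum(abs(meas$tetMass - abs(fvol))),
                       foldingCount = sum(fvol <= 0))
  }
  final <- distortionDiagnostics(f, mesh, rho)
  final$transportCost <- transportCost(f, mesh, rho)
  final$boundaryCost <- boundaryCost(gstar, mesh, rho)
  final$trace <- trace
  list(map = new("PLMap", coords = f, vertexIds = seq_len(n),
                 target = "cube"),
       diagnostics = final)
}
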