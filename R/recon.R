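# Bayesian refinement of a section stack: an overconstrained set of pairwise
# SVF registrations between three modalities (reference slice M, stains A and
# B) is reduced to the 3S-1 transforms of a spanning tree by robust L1
# inference, solved as a linear program. First-order SVF composition
# (addition of velocities) is used inside this refinement only; final
# per-image transforms are exponentiated.

#' Build the measurement/spanning-tree registration graph for a stack
#'
#' Nodes are the 3S images (reference slice, stain A, stain B per section).
#' Measurements: stain-to-reference and stain-to-stain within each section
#' (3S), plus directed intra-modality neighbour registrations at offsets 1
#' and 2 in both directions for each modality (12S-18), totalling 15S-18.
#' The latent spanning tree holds the S-1 reference-chain transforms and the
#' 2S stain-to-reference transforms (3S-1 edges).
#'
#' @param stack a [make_section_stack()] stack, or an integer section count.
#' @return object of class `registration_graph` with the measurement table,
#'   latent edge table and the `{-1,0,1}` path matrix (full column rank).
#' @export
build_registration_graph <- function(stack) {
  S <- if (inherits(stack, "section_stack")) stack$S else as.integer(stack)
  if (S < 3) stop("graph construction requires S >= 3 sections")
  mods <- c("M", "A", "B")
  node_id <- function(mod, s) paste0(mod, s)
  latent <- rbind(
    if (S > 1) data.frame(from = node_id("M", 1:(S - 1)),
                          to = node_id("M", 2:S), type = "MM"),
    data.frame(from = node_id("A", 1:S), to = node_id("M", 1:S),
               type = "AM"),
    data.frame(from = node_id("B", 1:S), to = node_id("M", 1:S),
               type = "BM"))
  latent$id <- seq_len(nrow(latent))
  measured <- rbind(
    data.frame(from = node_id("A", 1:S), to = node_id("M", 1:S),
               type = "AM", offset = 0),
    data.frame(from = node_id("B", 1:S), to = node_id("M", 1:S),
               type = "BM", offset = 0),
    data.frame(from = node_id("B", 1:S), to = node_id("A", 1:S),
               type = "BA", offset = 0))
  for (mod in mods) for (o in 1:2) {
    s <- 1:(S - o)
    measured <- rbind(measured,
      data.frame(from = node_id(mod, s), to = node_id(mod, s + o),
                 type = paste0(mod, "nbr"), offset = o),
      data.frame(from = node_id(mod, s + o), to = node_id(mod, s),
                 type = paste0(mod, "nbr"), offset = -o))
  }
  measured$id <- seq_len(nrow(measured))
  E <- nrow(latent)
  # signed chain from each node to the root M1 in latent-edge coordinates
  chain <- matrix(0, 3 * S, E,
                  dimnames = list(c(node_id("M", 1:S), node_id("A", 1:S),
                                    node_id("B", 1:S)), NULL))
  for (s in 2:S) {
    k <- which(latent$type == "MM")[s - 1]
    chain[node_id("M", s), ] <- chain[node_id("M", s - 1), ]
    chain[node_id("M", s), k] <- chain[node_id("M", s), k] - 1
  }
  for (s in 1:S) {
    ka <- which(latent$type == "AM")[s]
    kb <- which(latent$type == "BM")[s]
    chain[node_id("A", s), ] <- chain[node_id("M", s), ]
    chain[node_id("A", s), ka] <- 1
    chain[node_id("B", s), ] <- chain[node_id("M", s), ]
    chain[node_id("B", s), kb] <- 1
  }
  P <- chain[measured$from, , drop = FALSE] -
       chain[measured$to, , drop = FALSE]
  rownames(P) <- NULL
  structure(list(S = S, latent = latent, measured = measured, P = P,
                 svfs = NULL, spacing = NULL, shape2d =
                   if (inherits(stack, "section_stack")) stack$shape2d
                   else NULL),
            class = "registration_graph")
}

# Image of a node id from the stack.
node_image <- function(stack, id) {
  mod <- substr(id, 1, 1)
  s <- as.integer(substring(id, 2))
  switch(mod, M = stack$sections[[s]]$M, A = stack$sections[[s]]$A,
         B = stack$sections[[s]]$B)
}

#' Compute all pairwise SVF measurements of a registration graph
#'
#' Runs [register_section_nonlinear()] for every measured edge (moving =
#' `from`, fixed = `to`), after monotone histogram matching for
#' cross-modality pairs. SVFs are stored on the shared B-spline control grid.
#'
#' @param stack a [make_section_stack()] stack.
#' @param graph a [build_registration_graph()] graph.
#' @param cp_spacing control-point spacing in voxels.
#' @param lncc_sigma local NCC window sd in voxels.
#' @param reg_weight bending-energy weight.
#' @param maxit optimiser iterations per edge.
#' @return the graph with `svfs` (list of control-value arrays) populated.
#' @export
run_pairwise_registrations <- function(stack, graph, cp_spacing = 8,
                                       lncc_sigma = 3, reg_weight = 0.01,
                                       maxit = 30) {
  sh <- stack$shape2d
  svfs <- vector("list", nrow(graph$measured))
  for (k in seq_len(nrow(graph$measured))) {
    e <- graph$measured[k, ]
    mov <- node_image(stack, e$from)
    fix <- node_image(stack, e$to)
    cross <- substr(e$from, 1, 1) != substr(e$to, 1, 1)
    if (cross) mov <- match_histogram(mov, fix)
    res <- tryCatch(
      register_section_nonlinear(mov, fix, cp_spacing = cp_spacing,
                                 lncc_radius = lncc_sigma,
                                 reg_weight = reg_weight, maxit = maxit),
      error = function(err) stop(sprintf(
        "registration failed for edge %s->%s: %s", e$from, e$to,
        conditionMessage(err)), call. = FALSE))
    svfs[[k]] <- res$control
  }
  graph$svfs <- svfs
  graph$spacing <- cp_spacing
  graph$shape2d <- sh
  graph
}

#' Nonlinear registration of one section pair
#'
#' B-spline-parameterised SVF maximising local normalised cross-correlation
#' minus a bending-energy penalty (images must share a grid; linear
#' initialisation is assumed done).
#'
#' @param moving_image,fixed_image 2D arrays on a common grid.
#' @param cp_spacing control-point spacing in voxels (the tool's CLI exposes
#'   this in mm; 10 mm is the conventional default).
#' @param lncc_radius Gaussian window sd of the local NCC, in voxels.
#' @param reg_weight bending-energy weight.
#' @param maxit optimiser iterations.
#' @param init optional initial control values.
#' @return list with `v` (dense [velocity_field()]), `control` values,
#'   `spacing` and the objective trace.
#' @export
register_section_nonlinear <- function(moving_image, fixed_image,
                                       cp_spacing = 8, lncc_radius = 3,
                                       reg_weight = 0.01, maxit = 40,
                                       init = NULL) {
  if (stats::sd(as.vector(fixed_image)) == 0)
    stop("fixed image is constant: local NCC undefined")
  if (stats::sd(as.vector(moving_image)) == 0)
    stop("moving image is constant: local NCC undefined")
  optimize_svf(metric_lncc(fixed_image, moving_image, sigma = lncc_radius),
               dim(fixed_image), cp_spacing, reg_weight = reg_weight,
               maxit = maxit, init = init)
}

# Weighted least-absolute-deviation solve of one decoupled LP instance:
# min_x sum_k w_k |y_k - (P x)_k| via slack variables and the simplex method.
lad_lp <- function(P, y, w) {
  K <- nrow(P); E <- ncol(P)
  if (max(abs(y)) < 1e-12)
    return(list(x = rep(0, E), value = 0))
  # simplex expects a non-negative right-hand side: flip rows as needed
  flip <- y < 0
  Pf <- P; Pf[flip, ] <- -Pf[flip, , drop = FALSE]
  yf <- abs(y)
  obj <- c(rep(0, 2 * E), w, w)
  A3 <- cbind(Pf, -Pf, diag(K), -diag(K))
  sol <- boot::simplex(a = obj, A3 = A3, b3 = yf, maxi = FALSE)
  if (sol$solved == -1)
    stop("L1 refinement linear program infeasible (K=", K, ", E=", E, ")")
  x <- sol$soln[seq_len(E)] - sol$soln[E + seq_len(E)]
  list(x = x, value = sol$value)
}

#' Robust L1 inference of the spanning-tree SVFs
#'
#' Models every measured SVF as the signed sum (first-order composition) of
#' the latent spanning-tree SVFs along its tree path, with Laplace noise, and
#' minimises the weighted L1 residual. The problem decouples into an
#' independent least-absolute-deviation linear program per control point and
#' per vector component, each solved with the simplex method.
#'
#' @param graph a graph with measurements populated (or a list
#'   `list(P = path matrix, Y = K x m matrix of measurement coordinates)` for
#'   direct use).
#' @param weights_by_type named numeric vector of per-measurement-type
#'   weights (default 1 for every type).
#' @return list with `latents` (E x m matrix of latent coordinates, or a list
#'   of control arrays when called on a populated graph), and the LP
#'   objective `value`.
#' @export
refine_bayesian <- function(graph, weights_by_type = NULL) {
  if (inherits(graph, "registration_graph")) {
    if (is.null(graph$svfs)) stop("graph has no measurements: run ",
                                  "run_pairwise_registrations() first")
    cdim <- dim(graph$svfs[[1]])
    Y <- do.call(rbind, lapply(graph$svfs, as.vector))
    types <- graph$measured$type
    P <- graph$P
  } else {
    Y <- graph$Y; P <- graph$P
    types <- rep("all", nrow(Y))
    cdim <- NULL
  }
  if (qr(P)$rank < ncol(P))
    stop("path matrix is rank deficient: latent transforms unidentifiable")
  w <- rep(1, nrow(Y))
  if (!is.null(weights_by_type)) {
    hit <- types %in% names(weights_by_type)
    w[hit] <- weights_by_type[types[hit]]
  }
  X <- matrix(0, ncol(P), ncol(Y))
  val <- 0
  for (m in seq_len(ncol(Y))) {
    sol <- lad_lp(P, Y[, m], w)
    X[, m] <- sol$x
    val <- val + sol$value
  }
  latents <- if (!is.null(cdim)) {
    lapply(seq_len(nrow(X)), function(e) array(X[e, ], cdim))
  } else X
  list(latents = latents, value = val, weights = w)
}

# Weighted least-squares baseline on the same decoupled system.
solve_tree_l2 <- function(P, Y, w = rep(1, nrow(P))) {
  sw <- sqrt(w)
  qr.coef(qr(P * sw), Y * sw)
}

# Latent control array for a named tree edge.
latent_control <- function(graph, latents, type, s) {
  idx <- which(graph$latent$type == type)[s]
  latents[[idx]]
}

#' Final stain-to-reference transforms from refined latents
#'
#' Expands the latent stain-to-reference control grids to dense SVFs and
#' exponentiates them (composition with the reference chain happens in the
#' log domain upstream; the stain-to-slice edge is the transform needed to
#' reassemble each section).
#'
#' @param graph populated [build_registration_graph()] graph.
#' @param latents latent control arrays from [refine_bayesian()].
#' @return list per section with `A` and `B` [velocity_field()]s.
#' @export
stack_transforms <- function(graph, latents) {
  sh <- graph$shape2d
  lapply(seq_len(graph$S), function(s) {
    list(A = velocity_field(array(bspline_field(
           latent_control(graph, latents, "AM", s), graph$spacing, sh),
           c(sh, 2))),
         B = velocity_field(array(bspline_field(
           latent_control(graph, latents, "BM", s), graph$spacing, sh),
           c(sh, 2))))
  })
}

# Baseline: independent per-section transforms straight from the measured
# stain-to-reference registrations.
independent_transforms <- function(graph) {
  sh <- graph$shape2d
  lapply(seq_len(graph$S), function(s) {
    ka <- which(graph$measured$type == "AM")[s]
    kb <- which(graph$measured$type == "BM")[s]
    list(A = velocity_field(array(bspline_field(graph$svfs[[ka]],
           graph$spacing, sh), c(sh, 2))),
         B = velocity_field(array(bspline_field(graph$svfs[[kb]],
           graph$spacing, sh), c(sh, 2))))
  })
}

# Baseline: neighbour-only chaining. Each stain section is registered only
# through the chain of offset-1 neighbour measurements down to section 1,
# anchored by the section-1 stain-to-reference measurement (first-order
# composition). Smooth, but curvature of the anatomy leaks into the
# transforms (the "banana effect").
chain_transforms <- function(graph) {
  sh <- graph$shape2d
  lapply(seq_len(graph$S), function(s) {
    one <- function(mod) {
      type <- paste0(mod, "nbr")
      acc <- graph$svfs[[1]] * 0
      ksel <- which(graph$measured$type == type &
                    graph$measured$offset == -1)
      # edges (s' -> s'-1): walk s down to 1
      if (s > 1) for (t in s:2) {
        e <- ksel[t - 1]
        acc <- acc + graph$svfs[[e]]
      }
      anchor <- which(graph$measured$type == paste0(mod, "M"))[1]
      acc <- acc + graph$svfs[[anchor]]
      velocity_field(array(bspline_field(acc, graph$spacing, sh), c(sh, 2)))
    }
    list(A = one("A"), B = one("B"))
  })
}

#' Landmark-based evaluation of a reconstruction
#'
#' Maps each planted stain landmark into reference coordinates through the
#' estimated transform and reports the Euclidean error against its true
#' counterpart, in voxels and mm, plus a cross-section smoothness score: the
#' mean norm of second differences, along the stack, of the intensity
#' centroid of each reconstructed stain section. Neighbour-only chaining
#' straightens curved anatomy and therefore scores *smoother* than the true
#' reconstruction even while its landmark error is larger — the classic
#' banana effect, made visible by reporting both numbers.
#'
#' @param stack a [make_section_stack()] stack with planted landmarks.
#' @param transforms per-section list with `A`/`B` [velocity_field()]s
#'   mapping each stain to its reference slice (as from
#'   [stack_transforms()]).
#' @param voxel_size mm per voxel (scalar).
#' @return list with per-landmark `errors_voxel`, `mean`, `sd`, `mean_mm`,
#'   `sd_mm` and `smoothness`.
#' @export
evaluate_reconstruction <- function(stack, transforms, voxel_size = 1) {
  errs <- c()
  centroid <- matrix(0, stack$S, 2)
  base <- voxel_coords(stack$shape2d)
  for (s in seq_len(stack$S)) {
    for (mod in c("A", "B")) {
      lm <- stack$sections[[s]][[paste0("landmarks_", mod)]]
      if (is.null(lm) || nrow(lm$p) == 0) next
      v <- transforms[[s]][[mod]]
      dinv <- invert(v, 6)
      qhat <- lm$p + sample_disp(dinv, lm$p)
      errs <- c(errs, sqrt(rowSums((qhat - lm$q)^2)))
    }
    rec <- warp(stack$sections[[s]]$A, exp_svf(transforms[[s]]$A, 6))
    w <- pmax(as.vector(rec) - min(rec), 0)
    centroid[s, ] <- if (sum(w) > 0) colSums(base * w) / sum(w)
                     else (stack$shape2d + 1) / 2   # empty reconstruction
  }
  if (length(errs) == 0) stop("stack has no planted landmarks to evaluate")
  smooth <- if (stack$S >= 3) {
    d2 <- diff(centroid, differences = 2)
    mean(sqrt(rowSums(d2^2)))
  } else NA_real_
  list(errors_voxel = errs, mean = mean(errs), sd = stats::sd(errs),
       mean_mm = mean(errs) * voxel_size, sd_mm = stats::sd(errs) * voxel_size,
       smoothness = smooth)
}
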