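# End-to-end orchestration: decompose -> PCA (cQ) -> PLS-FMA (cT, cTew)
# -> coupling plane/grid/path -> vdW overlaps -> contact classification,
# with optional T/R difference-mode and transition analyses and optional
# CSV/JSON artifact output. Outputs are a pure function of (inputs,
# parameters); every stage logs its parameters when `verbose`.

#' Run the full tertiary-quaternary coupling analysis
#'
#' @param traj Raw `qt_trajectory` (one run or several concatenated runs).
#' @param reference Reference `structure_frame` (T-state).
#' @param partition Chain partition; default the reference's.
#' @param t_state,r_state Optional end-state `structure_frame`s enabling
#'   the T-R difference decomposition, plane anchors, anchor path and
#'   transition verdict.
#' @param k_max Largest PLS component count scanned by cross-validation.
#' @param n_grid Grid divisions per plane axis (default 20).
#' @param cutoff Contact cutoff in nm (default 0.3).
#' @param transition_threshold Covered T-R fraction calling a transition
#'   (default 0.8).
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param verbose Log stage parameters to the console.
#' @return Object of class `qt_pipeline`: decomposition, PCA, modes (cQ,
#'   cT, cTew and, with end states, the T-R modes), component selection,
#'   projections (target and model prediction with split point), plane,
#'   grid, path, overlap surface, classified contacts, scalar-product
#'   table, and (with end states) the transition verdict.
#' @export
run_pipeline <- function(traj, reference, partition = reference$partition,
                         t_state = NULL, r_state = NULL, k_max = 20L,
                         n_grid = 20L, cutoff = 0.3,
                         transition_threshold = 0.8, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("decompose: %d frames, %d chains", n_frames(traj), length(partition))
  decomp <- decompose_trajectory(traj, reference, partition)
  qfit <- remove_global_fit(decomp$quaternary, reference)
  say("pca: quaternary-only trajectory")
  pca <- traj_pca(qfit)
  cQ <- pca_mode(pca, 1L, role = "cQ")
  target <- project_mode(qfit, cQ)
  say("fma: k_max = %d, split-half cross-validation", k_max)
  sel <- select_components(decomp$tertiary, target, k_max)
  model <- sel$split_model
  final <- sel$model
  cT <- final$mode_cT
  cTew <- ensemble_weight(final)
  say("fma: k_best = %d, fit_r = %.3f, cv_r = %.3f", sel$k_best,
      model$fit_r, model$cv_r)
  tr <- NULL
  verdict <- NULL
  anchors <- NULL
  if (!is.null(t_state) && !is.null(r_state)) {
    tr <- tr_difference(t_state, r_state, partition)
    verdict <- detect_transition(traj, tr, transition_threshold)
    anchors <- list(T = tr$t_state, R = tr$r_fit)
    say("transition: max fraction %.3f (%s)", verdict$max_fraction,
        if (verdict$is_transition) "transition" else "no transition")
  }
  rawfit <- remove_global_fit(traj, reference)
  say("plane: projecting %d frames onto (cQ, cTew)", n_frames(traj))
  plane <- project_plane(rawfit, cQ, cTew, origin = reference,
                         anchors = anchors)
  grid <- build_grid(plane, n_grid)
  path <- if (!is.null(anchors)) anchor_path(grid)
          else make_path(grid, cell_of(grid, plane$points[1L, ]),
                         cell_of(grid, plane$points[n_frames(traj), ]))
  say("grid: %d x %d cells, path of %d cells", n_grid, n_grid,
      nrow(path$cells))
  surf <- overlap_surface(grid, partition)
  contacts <- classify_contacts(contact_profile(path, partition, cutoff))
  modes <- list(cQ = cQ, cT = cT, cTew = cTew)
  if (!is.null(tr)) {
    modes$TR_full <- tr$full
    if (!is.null(tr$tertiary)) modes$TR_tertiary <- tr$tertiary
    if (!is.null(tr$quaternary)) modes$TR_quaternary <- tr$quaternary
  }
  scalar_products <- overlap_table(modes)
  # model prediction over all frames (Fig. 2-style series)
  pred <- model$ybar +
    as.numeric(sweep(decomp$tertiary$xyz, 2L, model$xbar) %*% model$beta)
  result <- structure(list(
    decomposition = decomp, pca = pca, modes = modes,
    selection = list(k_best = sel$k_best, cv_curve = sel$cv_curve),
    model = model, final_model = final,
    projections = data.frame(frame = seq_len(n_frames(traj)),
                             target = target, prediction = pred),
    split_point = model$split_point, fit_r = model$fit_r,
    cv_r = model$cv_r, plane = plane, grid = grid, path = path,
    overlap_surface = surf, contacts = contacts,
    scalar_products = scalar_products, transition = verdict,
    params = list(k_max = k_max, n_grid = n_grid, cutoff = cutoff,
                  transition_threshold = transition_threshold)),
    class = "qt_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.qt_pipeline <- function(x, ...) {
  cat("qt_pipeline result\n")
  cat(sprintf("  frames: %d, chains: %d\n", nrow(x$projections),
              length(x$decomposition$reference$partition)))
  cat(sprintf("  cQ explained fraction: %.3f\n", x$pca$explained[1L]))
  cat(sprintf("  PLS components: %d, fit_r = %.3f, cv_r = %.3f\n",
              x$selection$k_best, x$fit_r, x$cv_r))
  cat(sprintf("  contacts: %d pair(s): %s\n", nrow(x$contacts$pairs),
              paste(sprintf("%s %d", names(table(x$contacts$pairs$class)),
                            table(x$contacts$pairs$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits projections.csv (per-frame target and model prediction with the
#' split point), plane.csv, overlap_grid.csv, contacts.csv,
#' scalar_products.csv, poses.csv and modes.json.
#'
#' @param result A `qt_pipeline`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = ",", row.names = FALSE,
    quote = FALSE)
  proj <- result$projections
  proj$half <- ifelse(proj$frame <= result$split_point, "model",
                      "validation")
  w(proj, "projections.csv")
  w(data.frame(frame = seq_len(nrow(result$plane$points)),
               a = result$plane$points[, 1], b = result$plane$points[, 2]),
    "plane.csv")
  surf <- result$overlap_surface
  grid_df <- data.frame(
    i = rep(seq_len(nrow(surf)), ncol(surf)),
    j = rep(seq_len(ncol(surf)), each = nrow(surf)),
    a = rep(result$grid$centers_a, ncol(surf)),
    b = rep(result$grid$centers_b, each = nrow(surf)),
    overlap = as.vector(surf))
  w(grid_df, "overlap_grid.csv")
  cp <- result$contacts
  w(cbind(cp$pairs,
          presence = apply(cp$presence, 1L, function(p)
            paste(as.integer(p), collapse = ""))),
    "contacts.csv")
  sp <- as.data.frame(result$scalar_products)
  sp <- cbind(mode = rownames(result$scalar_products), sp)
  w(sp, "scalar_products.csv")
  w(pose_table(result$decomposition), "poses.csv")
  jsonlite::write_json(
    lapply(result$modes, function(m) list(role = m$role, vector = m$vector)),
    file.path(out_dir, "modes.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
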