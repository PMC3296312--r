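# End-to-end simulation protocol: generate independent training and testing
# sets, train SVS variants (2D / 3D / combined), apply every method to every
# test, and summarize errors overall and within the selection groups.

variant_cols <- function(variant) {
  v <- gsub("&", "", variant, fixed = TRUE)
  list(sel = paste0("sel_", v), vd = paste0("vd_svs_", v),
       dsc = paste0("dsc_svs_", v))
}

eval_test_case <- function(tc, B, staple_args) {
  fac <- dissimilarity_factors(tc$raters, B = B)
  fusions <- lapply(svs_methods, run_base_fuser, raters = tc$raters,
                    staple_args = staple_args)
  names(fusions) <- svs_methods
  sc <- score_test(tc$truth, fusions)
  list(fac = fac, fusions = fusions, sc = sc,
       vds = vapply(fusions, function(f) vd(f, tc$truth)$v_D, numeric(1)),
       dscs = vapply(fusions, function(f) dsc(f, tc$truth), numeric(1)))
}

#' Run the simulation protocol end to end
#'
#' Generates one training and one independent testing set per requested
#' dimensionality (each a \code{n_grid} x \code{n_grid} grid of Gaussian
#' (mu, sd) deformation distributions with \code{raters_per_test} images per
#' test), trains the requested SVS variants on the training set(s), applies
#' STAPLE, Vote, SBA and every SVS variant to each testing-set case, and
#' evaluates v_D and DSC of all results against the ground truth. Tests are
#' materialized lazily one at a time. The canonical protocol uses
#' \code{n_grid = 25} (625 tests of 10 raters, 6,250 images per set); the
#' default here is a 100-test scaled version of the same grid.
#'
#' Tests whose raters are unanimous are reported but flagged and excluded
#' from the group statistics (there is nothing to select or fuse). The group
#' labels partition the remaining tests by the method the reference SVS
#' variant (the combined one when trained, otherwise the last variant)
#' selected.
#'
#' @param test_dims character vector of testing-set dimensionalities among
#'   \code{"2d"}, \code{"3d"}.
#' @param variants SVS variants to train among \code{"2d"}, \code{"3d"},
#'   \code{"2d3d"} (combined training sets). Every trained variant is applied
#'   to every testing set, so cross-dimensional application (e.g. a 2D-trained
#'   selector on 3D tests) falls out directly.
#' @param n_grid points per axis of the (mu, sd) grid for both sets.
#' @param raters_per_test deformed images per test (>= 2; the dissimilarity
#'   factors are undefined for a single rater).
#' @param seed_train,seed_test independent protocol seeds; equal seeds are an
#'   error (the sets must not share RNG substreams).
#' @param span LOESS span for the scoring surfaces.
#' @param B odd virtual-rater count.
#' @param n_pilot calibration pilot size per dimensionality (default: the
#'   \code{\link{calibrate_sigma}} per-generator defaults).
#' @param spec_2d,spec_3d shape specifications.
#' @param staple_args extra arguments for \code{\link{fuse_staple}}.
#' @param out_dir optional directory; when given, the per-test records (CSV)
#'   and the summary (JSON) are written there.
#' @param verbose log per-test progress.
#' @return an object of class \code{protocol_report}: list with
#'   \code{records} (one row per test), \code{summary} (per set, group and
#'   method aggregates), \code{models} (the trained \code{svs_model}s) and
#'   \code{config}.
#' @export
run_protocol <- function(test_dims = "2d", variants = "2d", n_grid = 10L,
                         raters_per_test = 10L, seed_train = 1L,
                         seed_test = 2L, span = 0.25, B = 99L,
                         n_pilot = NULL, spec_2d = shape_spec_2d(),
                         spec_3d = shape_spec_3d(), staple_args = list(),
                         out_dir = NULL, verbose = FALSE) {
  test_dims <- match.arg(test_dims, c("2d", "3d"), several.ok = TRUE)
  variants <- match.arg(variants, c("2d", "3d", "2d3d"), several.ok = TRUE)
  if (raters_per_test < 2L) {
    stop("raters_per_test must be >= 2: dissimilarity factors (and fusion ",
         "selection) are undefined for a single rater")
  }
  if (identical(as.integer(seed_train), as.integer(seed_test))) {
    stop("seed_train and seed_test must differ: training and testing sets ",
         "would share RNG substreams")
  }
  specs <- list("2d" = spec_2d, "3d" = spec_3d)
  train_dims <- unique(unlist(lapply(variants, function(v) {
    if (v == "2d3d") c("2d", "3d") else v
  })))
  all_dims <- union(train_dims, test_dims)

  sigma <- lapply(all_dims, function(d) {
    calibrate_sigma(d, n_pilot = n_pilot, seed = seed_train, spec = specs[[d]])
  })
  names(sigma) <- all_dims

  say <- function(...) if (verbose) message(...)

  # --- training tables ---
  train_points <- lapply(train_dims, function(d) {
    plan <- build_protocol(d, n_grid = n_grid,
                           raters_per_test = raters_per_test,
                           seed = seed_train, sigma_max = sigma[[d]],
                           spec = specs[[d]])
    rows <- lapply(seq_len(nrow(plan)), function(i) {
      say("training ", d, " test ", i, "/", nrow(plan))
      tc <- make_test_case(plan, i)
      ec <- eval_test_case(tc, B, staple_args)
      data.frame(d_c = ec$fac$d_c, d_r = ec$fac$d_r,
                 s_STAPLE = ec$sc$s[["STAPLE"]], s_VOTE = ec$sc$s[["VOTE"]],
                 s_SBA = ec$sc$s[["SBA"]], degenerate = ec$sc$degenerate,
                 unanimous = ec$fac$unanimous)
    })
    do.call(rbind, rows)
  })
  names(train_points) <- train_dims

  models <- lapply(variants, function(v) {
    pts <- if (v == "2d3d") do.call(rbind, train_points[c("2d", "3d")])
           else train_points[[v]]
    svs_train_points(pts, span = span,
                     provenance = list(set_id = paste0("sim-", v),
                                       seed = as.integer(seed_train),
                                       n_tests = nrow(pts)))
  })
  names(models) <- variants
  ref_variant <- if ("2d3d" %in% variants) "2d3d" else variants[length(variants)]

  # --- testing phase ---
  records <- list()
  for (d in test_dims) {
    plan <- build_protocol(d, n_grid = n_grid,
                           raters_per_test = raters_per_test,
                           seed = seed_test, sigma_max = sigma[[d]],
                           spec = specs[[d]])
    for (i in seq_len(nrow(plan))) {
      say("testing ", d, " test ", i, "/", nrow(plan))
      tc <- make_test_case(plan, i)
      ec <- eval_test_case(tc, B, staple_args)
      rec <- data.frame(set = d, test_id = i, mu_fs = tc$mu_fs,
                        sd_fs = tc$sd_fs, d_c = ec$fac$d_c,
                        d_r = ec$fac$d_r, unanimous = ec$fac$unanimous,
                        degenerate = ec$sc$degenerate)
      for (m in svs_methods) {
        rec[[paste0("vd_", m)]] <- ec$vds[[m]]
        rec[[paste0("dsc_", m)]] <- ec$dscs[[m]]
      }
      for (v in variants) {
        cols <- variant_cols(v)
        if (ec$fac$unanimous) {
          # nothing to fuse: the input is returned, all methods coincide
          rec[[cols$sel]] <- "UNANIMOUS"
          rec[[cols$vd]] <- vd(tc$raters$raters[[1L]], tc$truth)$v_D
          rec[[cols$dsc]] <- dsc(tc$raters$raters[[1L]], tc$truth)
        } else {
          s <- svs_scores(models[[v]], ec$fac$d_c, ec$fac$d_r)
          top <- which(s >= max(s) - 1e-9)
          if (length(top) == 1L) {
            m <- svs_methods[top]
            rec[[cols$sel]] <- m
            rec[[cols$vd]] <- ec$vds[[m]]
            rec[[cols$dsc]] <- ec$dscs[[m]]
          } else {
            fused <- meta_fuse(ec$fusions, pmax(s, 0))
            rec[[cols$sel]] <- "META"
            rec[[cols$vd]] <- vd(fused, tc$truth)$v_D
            rec[[cols$dsc]] <- dsc(fused, tc$truth)
          }
        }
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, records)
  records$group <- ifelse(records$unanimous, NA_character_,
                          paste0("Group ", records[[variant_cols(ref_variant)$sel]]))

  report <- structure(
    list(records = records,
         summary = summarize_protocol(records, variants),
         models = models,
         config = list(test_dims = test_dims, variants = variants,
                       ref_variant = ref_variant, n_grid = n_grid,
                       raters_per_test = raters_per_test,
                       seed_train = as.integer(seed_train),
                       seed_test = as.integer(seed_test), span = span,
                       B = as.integer(B), n_pilot = n_pilot,
                       sigma_max = lapply(sigma, as.numeric))),
    class = "protocol_report")
  if (!is.null(out_dir)) write_protocol_report(report, out_dir)
  report
}

method_columns <- function(records, variants) {
  c(svs_methods, vapply(variants, function(v) paste0("svs_", gsub("&", "", v)),
                        character(1)))
}

summarize_protocol <- function(records, variants) {
  out <- list()
  for (d in unique(records$set)) {
    sub <- records[records$set == d & !records$unanimous, , drop = FALSE]
    if (nrow(sub) == 0L) next
    groups <- c("all", sort(unique(sub$group)))
    for (g in groups) {
      gs <- if (g == "all") sub else sub[sub$group == g, , drop = FALSE]
      for (m in method_columns(records, variants)) {
        vdc <- gs[[paste0("vd_", m)]]
        dsb <- gs[[paste0("dsc_", m)]]
        out[[length(out) + 1L]] <- data.frame(
          set = d, group = g, method = m, n = nrow(gs),
          mean_vd = mean(vdc), median_vd = stats::median(vdc),
          mean_dsc = mean(dsb), median_dsc = stats::median(dsb))
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("<protocol_report> ", nrow(x$records), " tests | sets: ",
      paste(unique(x$records$set), collapse = ", "), " | variants: ",
      paste(x$config$variants, collapse = ", "), "\n", sep = "")
  print(x$summary[x$summary$group == "all", ], row.names = FALSE)
  invisible(x)
}

#' Center per-test performance on a reference method
#'
#' Subtracts the reference method's v_D and DSC from every method's values,
#' test by test, the standard way these protocols are visualized (reference
#' columns become identically zero). Centering is a per-test shift, so the
#' ordering of methods within a test is preserved.
#'
#' @param report a \code{\link{run_protocol}} report.
#' @param reference method column suffix to center on (default \code{"VOTE"}).
#' @return the records data frame with centered \code{vd_*} and \code{dsc_*}
#'   columns.
#' @export
centered_stats <- function(report, reference = "VOTE") {
  stopifnot(inherits(report, "protocol_report"))
  rec <- report$records
  ref_vd <- rec[[paste0("vd_", reference)]]
  ref_dsc <- rec[[paste0("dsc_", reference)]]
  if (is.null(ref_vd)) stop("reference method '", reference, "' not in report")
  for (cn in names(rec)) {
    if (startsWith(cn, "vd_")) rec[[cn]] <- rec[[cn]] - ref_vd
    if (startsWith(cn, "dsc_")) rec[[cn]] <- rec[[cn]] - ref_dsc
  }
  rec
}

#' Write a protocol report to disk
#'
#' Per-test records as CSV and the aggregate summary plus configuration as
#' JSON. Identical configuration and seeds reproduce byte-identical files.
#'
#' @param report a \code{\link{run_protocol}} report.
#' @param dir output directory (created if needed).
#' @export
write_protocol_report <- function(report, dir) {
  stopifnot(inherits(report, "protocol_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary, config = report$config),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
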