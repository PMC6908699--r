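# Linear-MALDI multicharge deconvolution: group +1/+2/+3 peaks of one
# protein into a charge family, average the implied neutral masses into a
# component (mass +/- SD), align two deconvolved profiles at 0.1% relative
# mass, and render the condition-vs-condition differential report.

#' Group multicharged peaks into charge families
#'
#' Greedy assignment from the most intense unassigned peak down: the seed
#' peak is hypothesised to be the singly protonated species with neutral
#' mass `M = mz - proton`; any unassigned peak whose neutral-mass estimate
#' at another allowed charge lies within `rel_tol * M` of `M` joins the
#' family. Every peak ends up in exactly one family; singletons are kept
#' (as charge 1).
#'
#' @param pl A linear-mode `peak_list`.
#' @param charges Allowed charge states (default 1:3).
#' @param rel_tol Relative mass tolerance (default 0.001, i.e. the 0.1%
#'   centroid-shift alignment window).
#' @return An object of class `charge_families`: a list of data.frames
#'   with columns `mz`, `intensity`, `charge`, `mass_estimate`.
#' @export
assign_charge_families <- function(pl, charges = 1:3, rel_tol = 0.001) {
  stopifnot(inherits(pl, "peak_list"))
  tab <- mass_table()
  pk <- pl$peaks
  n <- nrow(pk)
  fams <- list()
  if (!n) return(structure(fams, class = "charge_families"))
  assigned <- rep(FALSE, n)
  ord <- order(-pk$intensity, pk$mz)
  for (seed in ord) {
    if (assigned[seed]) next
    M <- mass_from_mz(pk$mz[seed], 1L, tab)
    members <- data.frame(mz = pk$mz[seed], intensity = pk$intensity[seed],
                          charge = 1L, mass_estimate = M)
    assigned[seed] <- TRUE
    for (z in setdiff(sort(charges), 1L)) {
      cand <- which(!assigned)
      if (!length(cand)) break
      est <- mass_from_mz(pk$mz[cand], z, tab)
      ok <- which(abs(est - M) <= rel_tol * M)
      if (length(ok)) {
        # nearest estimate wins; one peak per charge state
        best <- cand[ok[which.min(abs(est[ok] - M))]]
        members <- rbind(members, data.frame(
          mz = pk$mz[best], intensity = pk$intensity[best],
          charge = z, mass_estimate = mass_from_mz(pk$mz[best], z, tab)))
        assigned[best] <- TRUE
      }
    }
    fams[[length(fams) + 1L]] <- members
  }
  structure(fams, class = "charge_families")
}

#' Average a charge family into a deconvolved component
#'
#' Component mass is the unweighted mean of the per-member neutral-mass
#' estimates (`mz * z - z * proton`); the spread is the sample standard
#' deviation across charge states (0 for a single member), matching the
#' "mass +/- SD" reporting dialect of linear-MALDI profiling.
#'
#' @param family One element of a `charge_families` list.
#' @param label Optional component label.
#' @return One-row data.frame with columns `mass`, `sd`, `n_charges`,
#'   `label`.
#' @export
component_mass <- function(family, label = "") {
  if (is.null(family) || !nrow(family))
    stop("empty charge family", call. = FALSE)
  est <- family$mass_estimate
  data.frame(mass = mean(est),
             sd = if (length(est) > 1L) stats::sd(est) else 0,
             n_charges = length(est), label = label,
             stringsAsFactors = FALSE)
}

#' Deconvolve a linear profile into components
#'
#' [assign_charge_families()] followed by [component_mass()] on each
#' family; components are returned sorted by mass.
#'
#' @inheritParams assign_charge_families
#' @param label Label stamped on every component (defaults to the peak
#'   list's label).
#' @return data.frame of class `deconvolved_components` with columns
#'   `mass`, `sd`, `n_charges`, `label`.
#' @export
deconvolve_profile <- function(pl, charges = 1:3, rel_tol = 0.001,
                               label = NULL) {
  if (is.null(label)) label <- pl$label
  fams <- assign_charge_families(pl, charges, rel_tol)
  if (!length(fams)) {
    out <- data.frame(mass = numeric(0), sd = numeric(0),
                      n_charges = integer(0), label = character(0))
  } else {
    out <- do.call(rbind, lapply(fams, component_mass, label = label))
    out <- out[order(out$mass), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("deconvolved_components", "data.frame")
  out
}

#' Align two deconvolved profiles
#'
#' Greedy nearest-relative-mass matching: candidate pairs with
#' `|massA - massB| <= rel_tol * mean(massA, massB)` are taken smallest
#' relative difference first, each component used at most once; whatever
#' remains unpaired is condition-unique. Symmetric in A and B.
#'
#' @param a,b `deconvolved_components` data.frames.
#' @param rel_tol Relative mass tolerance (default 0.001).
#' @return An object of class `profile_comparison`: list with `shared`
#'   (paired rows, columns `mass_a`, `sd_a`, `mass_b`, `sd_b`,
#'   `rel_diff`), `unique_a`, `unique_b`, `rel_tol`.
#' @export
align_profiles <- function(a, b, rel_tol = 0.001) {
  na <- nrow(a); nb <- nrow(b)
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- NULL
  if (na && nb) {
    grid <- expand.grid(i = seq_len(na), j = seq_len(nb))
    grid$rel <- abs(a$mass[grid$i] - b$mass[grid$j]) /
      ((a$mass[grid$i] + b$mass[grid$j]) / 2)
    grid <- grid[grid$rel <= rel_tol, , drop = FALSE]
    grid <- grid[order(grid$rel, a$mass[grid$i]), , drop = FALSE]
    keep <- logical(nrow(grid))
    for (k in seq_len(nrow(grid))) {
      if (!used_a[grid$i[k]] && !used_b[grid$j[k]]) {
        keep[k] <- TRUE
        used_a[grid$i[k]] <- TRUE
        used_b[grid$j[k]] <- TRUE
      }
    }
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid)) {
      pairs <- data.frame(mass_a = a$mass[grid$i], sd_a = a$sd[grid$i],
                          mass_b = b$mass[grid$j], sd_b = b$sd[grid$j],
                          rel_diff = grid$rel)
      pairs <- pairs[order(pairs$mass_a), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(mass_a = numeric(0), sd_a = numeric(0),
                        mass_b = numeric(0), sd_b = numeric(0),
                        rel_diff = numeric(0))
  structure(list(shared = pairs,
                 unique_a = a[!used_a, , drop = FALSE],
                 unique_b = b[!used_b, , drop = FALSE],
                 rel_tol = rel_tol),
            class = "profile_comparison")
}

#' Render a differential report
#'
#' One TSV row per component: mass and SD rounded to integer Da and a
#' status in `{shared, A-only, B-only}`.
#'
#' @param comparison A `profile_comparison`.
#' @param path Optional output path; when given the TSV is written there.
#' @return data.frame with columns `mass_a`, `sd_a`, `mass_b`, `sd_b`,
#'   `status`, invisibly written to `path` when supplied.
#' @export
differential_report <- function(comparison, path = NULL) {
  sh <- comparison$shared
  ua <- comparison$unique_a
  ub <- comparison$unique_b
  rows <- rbind(
    if (nrow(sh)) data.frame(mass_a = round(sh$mass_a), sd_a = round(sh$sd_a),
                             mass_b = round(sh$mass_b), sd_b = round(sh$sd_b),
                             status = "shared"),
    if (nrow(ua)) data.frame(mass_a = round(ua$mass), sd_a = round(ua$sd),
                             mass_b = NA_real_, sd_b = NA_real_,
                             status = "A-only"),
    if (nrow(ub)) data.frame(mass_a = NA_real_, sd_a = NA_real_,
                             mass_b = round(ub$mass), sd_b = round(ub$sd),
                             status = "B-only"))
  if (is.null(rows))
    rows <- data.frame(mass_a = numeric(0), sd_a = numeric(0),
                       mass_b = numeric(0), sd_b = numeric(0),
                       status = character(0))
  rownames(rows) <- NULL
  if (!is.null(path))
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  rows
}

#' Merge replicate component sets within one condition
#'
#' Greedy grouping of components from several replicate spectra at the
#' same relative tolerance used for alignment; each group is averaged into
#' one component whose SD is taken across the contributing estimates.
#'
#' @param component_sets List of `deconvolved_components` data.frames.
#' @param rel_tol Relative mass tolerance.
#' @param label Label for the merged components.
#' @return A `deconvolved_components` data.frame.
#' @export
merge_components <- function(component_sets, rel_tol = 0.001, label = "") {
  all <- do.call(rbind, lapply(component_sets, function(d)
    as.data.frame(d)[, c("mass", "sd", "n_charges"), drop = FALSE]))
  if (is.null(all) || !nrow(all)) {
    out <- data.frame(mass = numeric(0), sd = numeric(0),
                      n_charges = integer(0), label = character(0))
    class(out) <- c("deconvolved_components", "data.frame")
    return(out)
  }
  all <- all[order(all$mass), , drop = FALSE]
  group <- cumsum(c(TRUE, diff(all$mass) >
                      rel_tol * (all$mass[-nrow(all)] + diff(all$mass) / 2)))
  merged <- do.call(rbind, lapply(split(all, group), function(g) {
    data.frame(mass = mean(g$mass),
               sd = if (nrow(g) > 1L) stats::sd(g$mass) else max(g$sd),
               n_charges = max(g$n_charges), label = label)
  }))
  rownames(merged) <- NULL
  class(merged) <- c("deconvolved_components", "data.frame")
  merged
}
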