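#' Configuration for the barcoded-amplicon read simulator
#'
#' Describes a complete synthetic experiment: which template panels to
#' draw molecules from (input copies are taken from each template set's
#' `input_copies`, per sample index), the base composition of the random
#' barcode positions, the per-molecule read-count (coverage) model, and the
#' per-base error model.
#'
#' The coverage model is negative binomial with mean `mean_coverage` and
#' dispersion `dispersion` (the NB `size`; larger = closer to Poisson).
#' `min_reads = 0` allows molecules to go unsequenced (dropout);
#' `min_reads = 1` resamples to a zero-truncated distribution so every
#' molecule is read at least once.
#'
#' Errors are applied independently per read: each base substitutes with
#' probability `sub_rate` (to one of the three other bases uniformly), is
#' masked to `N` with probability `n_rate`, and insertion/deletion events
#' occur at per-base rates `ins_rate`/`del_rate`, shifting the remainder of
#' the read (no re-padding) — exactly the frame shift the fixed-base filter
#' is designed to catch.  Each read's sample index is swapped to another
#' index with probability `swap_prob` (index hopping); whole molecules are
#' assigned to the wrong sample with probability `contam_prob` (primer
#' carry-over).
#'
#' @param templates A [template_set()] or list of template sets (e.g.
#'   short + long panels).
#' @param indices Named character vector of sample index sequences.
#' @param composition Named numeric vector of A/C/G/T probabilities for
#'   random barcode positions (normalized internally).
#' @param mean_coverage,dispersion NB read-count model per molecule.
#' @param min_reads Minimum reads per molecule (0 or 1 typical).
#' @param sub_rate,ins_rate,del_rate,n_rate Per-base error probabilities.
#' @param swap_prob Per-read index swap probability.
#' @param contam_prob Per-molecule cross-sample contamination probability.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(templates,
                              indices = c(A = "CGCTCATT"),
                              composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                              mean_coverage = 15,
                              dispersion = 4,
                              min_reads = 0L,
                              sub_rate = 0.0025,
                              ins_rate = 0.0005,
                              del_rate = 0.0005,
                              n_rate = 0.0005,
                              swap_prob = 0,
                              contam_prob = 0) {
  if (inherits(templates, "template_set")) templates <- list(templates)
  stopifnot(all(vapply(templates, inherits, TRUE, "template_set")))
  if (is.null(names(indices)) || anyDuplicated(names(indices)))
    stop("indices must be uniquely named")
  stopifnot(all(sort(names(composition)) == c("A", "C", "G", "T")))
  composition <- composition[c("A", "C", "G", "T")] / sum(composition)
  rates <- c(sub_rate, ins_rate, del_rate, n_rate, swap_prob, contam_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  structure(list(templates = templates, indices = indices,
                 composition = composition,
                 mean_coverage = mean_coverage, dispersion = dispersion,
                 min_reads = as.integer(min_reads),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, n_rate = n_rate,
                 swap_prob = swap_prob, contam_prob = contam_prob),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

#' Draw barcoded molecules
#'
#' Creates the pre-amplification molecule pool: for every template in every
#' template set and every sample index, `input_copies` molecules are drawn,
#' each with an independent random barcode (random positions from the
#' configured composition, fixed positions set to their designed bases).
#' Barcode collisions between molecules are possible and simply happen, as
#' in the real system; `contam_prob` molecules end up labeled with a wrong
#' sample index.
#'
#' @param config A [simulation_config()].
#' @return Data.frame with one row per molecule: `molecule_id`,
#'   `template_id`, `design`, `true_index`, `sample_index`, `barcode`.
#' @export
draw_molecules <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  idx_labels <- names(config$indices)
  out <- list()
  for (ts in config$templates) {
    design <- attr(ts, "design")
    rp <- design$random_positions
    for (t in seq_len(nrow(ts))) {
      copies <- ts$input_copies[t]
      if (is.na(copies) || copies <= 0) next
      for (ix in idx_labels) {
        n <- as.integer(copies)
        B <- matrix("", n, design$barcode_length)
        B[, rp] <- sample(.BASES, n * length(rp), replace = TRUE,
                          prob = config$composition)
        B[, design$fixed_positions] <-
          matrix(design$fixed_bases, n, length(design$fixed_positions),
                 byrow = TRUE)
        bc <- do.call(paste0, as.data.frame(B, stringsAsFactors = FALSE))
        sample_index <- rep(ix, n)
        if (config$contam_prob > 0 && length(idx_labels) > 1L) {
          hop <- stats::runif(n) < config$contam_prob
          if (any(hop))
            sample_index[hop] <- vapply(which(hop), function(i)
              sample(setdiff(idx_labels, ix), 1L), character(1))
        }
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = paste0(ts$template_id[t], "_", ix, "_m",
                               seq_len(n)),
          template_id = ts$template_id[t],
          design = design$name,
          true_index = ix,
          sample_index = sample_index,
          barcode = bc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# apply indel events to one read's character vector; events applied in
# decreasing position order so earlier positions keep their coordinates
.apply_indels <- function(chars, del_pos, ins_pos, ins_base) {
  ev <- rbind(
    if (length(del_pos)) cbind(del_pos, 0L, seq_along(del_pos)),
    if (length(ins_pos)) cbind(ins_pos, 1L, seq_along(ins_pos)))
  ev <- ev[order(-ev[, 1L]), , drop = FALSE]
  for (e in seq_len(nrow(ev))) {
    p <- ev[e, 1L]
    if (ev[e, 2L] == 0L) chars <- chars[-p]
    else chars <- append(chars, ins_base[ev[e, 3L]], after = p - 1L)
  }
  chars
}

#' Amplify and sequence a molecule pool
#'
#' For each molecule a read count is drawn from the configured coverage
#' model; each read is the molecule's full sequence (barcode followed by
#' the template target) with per-base substitutions, N-maskings,
#' insertions and deletions injected, and its sample index swapped with
#' probability `swap_prob`.  Every injected error is logged, so the ground
#' truth exactly reconciles with the emitted reads.
#'
#' @param molecules Output of [draw_molecules()].
#' @param config The [simulation_config()].
#' @return List with
#'   \describe{
#'     \item{reads}{observation data.frame (`read_id`, `sample_index`,
#'       `seq`) ready for the pipeline,}
#'     \item{molecules}{the molecule pool with an `n_reads` column,}
#'     \item{read_truth}{per read: molecule, template, true/final index,
#'       per-type error counts,}
#'     \item{errors}{per injected error: `read_id`, `type`
#'       (`sub`/`N`/`ins`/`del`), `position` (pre-indel coordinates),
#'       `from`, `to`.}
#'   }
#' @export
amplify_and_sequence <- function(molecules, config) {
  stopifnot(inherits(config, "simulation_config"))
  target_of <- new.env(parent = emptyenv())
  for (ts in config$templates)
    for (t in seq_len(nrow(ts)))
      assign(ts$template_id[t], ts$target_sequence[t], envir = target_of)
  idx_labels <- names(config$indices)

  n_mol <- nrow(molecules)
  n_reads <- stats::rnbinom(n_mol, mu = config$mean_coverage,
                            size = config$dispersion)
  if (config$min_reads > 0L) {
    low <- n_reads < config$min_reads
    while (any(low)) {
      n_reads[low] <- stats::rnbinom(sum(low), mu = config$mean_coverage,
                                     size = config$dispersion)
      low <- n_reads < config$min_reads
    }
  }
  molecules$n_reads <- n_reads

  reads_out <- list(); truth_out <- list(); err_out <- list()
  for (grp in split(seq_len(n_mol),
                    paste0(molecules$design, "\r",
                           molecules$sample_index))) {
    grp <- grp[molecules$n_reads[grp] > 0L]
    if (!length(grp)) next
    mol <- molecules[grp, , drop = FALSE]
    full <- paste0(mol$barcode,
                   unlist(mget(mol$template_id, envir = target_of)))
    L <- nchar(full[1])
    reps <- mol$n_reads
    mol_of_read <- rep(seq_len(nrow(mol)), reps)
    n <- length(mol_of_read)
    read_id <- paste0(rep(mol$molecule_id, reps), "_r",
                      sequence(reps))
    Mm <- .char_matrix(full, L)
    M <- Mm[mol_of_read, , drop = FALSE]

    # substitutions and N-masking (exclusive per cell)
    u <- stats::runif(n * L)
    sub_cells <- which(u < config$sub_rate)
    n_cells <- which(u >= config$sub_rate &
                     u < config$sub_rate + config$n_rate)
    err <- list()
    if (length(sub_cells)) {
      from <- M[sub_cells]
      off <- sample.int(3L, length(sub_cells), replace = TRUE)
      to <- .BASES[(match(from, .BASES) - 1L + off) %% 4L + 1L]
      M[sub_cells] <- to
      err[[length(err) + 1L]] <- data.frame(
        read_id = read_id[(sub_cells - 1L) %% n + 1L],
        type = "sub",
        position = (sub_cells - 1L) %/% n + 1L,
        from = from, to = to, stringsAsFactors = FALSE)
    }
    if (length(n_cells)) {
      from <- M[n_cells]
      M[n_cells] <- "N"
      err[[length(err) + 1L]] <- data.frame(
        read_id = read_id[(n_cells - 1L) %% n + 1L],
        type = "N",
        position = (n_cells - 1L) %/% n + 1L,
        from = from, to = "N", stringsAsFactors = FALSE)
    }

    # indels (per-read event counts; positions on pre-indel coordinates)
    n_ins <- stats::rbinom(n, L, config$ins_rate)
    n_del <- stats::rbinom(n, L, config$del_rate)
    affected <- which(n_ins + n_del > 0L)
    seqs <- character(n)
    clean <- setdiff(seq_len(n), affected)
    if (length(clean))
      seqs[clean] <- do.call(paste0,
                             as.data.frame(M[clean, , drop = FALSE],
                                           stringsAsFactors = FALSE))
    for (i in affected) {
      del_pos <- if (n_del[i]) sort(sample.int(L, n_del[i])) else integer(0)
      ins_pos <- if (n_ins[i]) sort(sample.int(L, n_ins[i])) else integer(0)
      ins_base <- if (n_ins[i]) sample(.BASES, n_ins[i], replace = TRUE)
                  else character(0)
      chars <- .apply_indels(M[i, ], del_pos, ins_pos, ins_base)
      seqs[i] <- paste(chars, collapse = "")
      if (n_del[i])
        err[[length(err) + 1L]] <- data.frame(
          read_id = read_id[i], type = "del", position = del_pos,
          from = M[i, del_pos], to = "", stringsAsFactors = FALSE)
      if (n_ins[i])
        err[[length(err) + 1L]] <- data.frame(
          read_id = read_id[i], type = "ins", position = ins_pos,
          from = "", to = ins_base, stringsAsFactors = FALSE)
    }

    # index swapping (per read)
    final_index <- rep(mol$sample_index, reps)
    swapped <- rep(FALSE, n)
    if (config$swap_prob > 0 && length(idx_labels) > 1L) {
      hop <- which(stats::runif(n) < config$swap_prob)
      for (i in hop)
        final_index[i] <- sample(setdiff(idx_labels, final_index[i]), 1L)
      swapped[hop] <- TRUE
    }

    reads_out[[length(reads_out) + 1L]] <- data.frame(
      read_id = read_id, sample_index = final_index, seq = seqs,
      stringsAsFactors = FALSE)
    truth_out[[length(truth_out) + 1L]] <- data.frame(
      read_id = read_id,
      molecule_id = rep(mol$molecule_id, reps),
      template_id = rep(mol$template_id, reps),
      true_index = rep(mol$true_index, reps),
      sample_index = final_index,
      swapped = swapped,
      n_sub = tabulate((sub_cells - 1L) %% n + 1L, nbins = n),
      n_N = tabulate((n_cells - 1L) %% n + 1L, nbins = n),
      n_ins = n_ins, n_del = n_del,
      stringsAsFactors = FALSE)
    if (length(err))
      err_out[[length(err_out) + 1L]] <- do.call(rbind, err)
  }
  list(reads = do.call(rbind, reads_out),
       molecules = molecules,
       read_truth = do.call(rbind, truth_out),
       errors = if (length(err_out)) do.call(rbind, err_out)
                else data.frame(read_id = character(0), type = character(0),
                                position = integer(0), from = character(0),
                                to = character(0), stringsAsFactors = FALSE))
}

#' Simulate a complete barcoded sequencing run
#'
#' Convenience wrapper: [draw_molecules()] then [amplify_and_sequence()],
#' under a single seed.  Output is byte-for-byte reproducible for a given
#' config and seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @return See [amplify_and_sequence()]; the config is attached as
#'   `$config`.
#' @export
simulate_reads <- function(config, seed = NULL) {
  out <- .seeded(seed, function() {
    mol <- draw_molecules(config)
    amplify_and_sequence(mol, config)
  })
  out$config <- config
  out$seed <- seed
  out
}

#' The study's eleven-template panel as a simulation preset
#'
#' Two identically composed samples (indices A and B) containing, per
#' sample, 40,000 / 40,000 / 4,000 / 300 / 100 / 20 copies of LT1-LT6 and
#' 20,000 / 20,000 / 4,000 / 4,000 / 4,000 copies of ST1-ST5, sequenced
#' with 0.25% per-base substitutions (midpoint of the 0.23-0.29% range
#' estimated for this chemistry), 0.05% + 0.05% insertion/deletion rates,
#' and mean coverage 15.
#'
#' @param copy_scale Multiplier on every template's input copies (use < 1
#'   for quick desk-scale runs; counts below 1 copy round to at least 1).
#' @param ... Overrides passed on to [simulation_config()].
#' @return A [simulation_config()]; pass it to [simulate_reads()].
#' @export
preset_paper_panel <- function(copy_scale = 1, ...) {
  panels <- default_templates("both")
  if (copy_scale != 1) {
    for (i in seq_along(panels)) {
      panels[[i]]$input_copies <-
        pmax(1, round(panels[[i]]$input_copies * copy_scale))
    }
  }
  simulation_config(templates = panels,
                    indices = c(A = "CGCTCATT", B = "GAGATTCC"),
                    ...)
}
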