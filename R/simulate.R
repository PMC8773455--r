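#' Simulation configuration
#'
#' Describes a synthetic multi-population control-region dataset: per
#' population a sample size and a haplogroup-frequency vector over leaves
#' (or any named nodes) of the motif tree; a Poisson rate of private
#' substitutions per sample; a per-sample probability of carrying one
#' point heteroplasmy (emitted as a two-base IUPAC code); the sequencing
#' window; and an optional planted haplotype-sharing fraction between the
#' first two populations.
#'
#' @param populations named list; each element is `list(n = <size>,
#'   freq = <named numeric summing to 1 over haplogroup names>)`.
#' @param seed integer seed; mandatory, so identical configs give
#'   byte-identical output.
#' @param private_rate expected number of private substitutions per sample
#'   (Poisson; default 1).
#' @param heteroplasmy_prob per-sample probability of one heteroplasmic
#'   base (default 0.005).
#' @param window sequencing [coord_window()] (default full control region).
#' @param shared_fraction optional fraction in \[0,1\]: the first two
#'   populations are generated so that this fraction of their distinct
#'   haplotypes is shared (each sample then carries a unique tag mutation,
#'   making every haplotype distinct within a population).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(populations, seed, private_rate = 1,
                       heteroplasmy_prob = 0.005,
                       window = standard_window("cr"),
                       shared_fraction = NULL) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  stopifnot(length(populations) >= 1L, private_rate >= 0,
            heteroplasmy_prob >= 0, heteroplasmy_prob <= 1)
  for (nm in names(populations)) {
    p <- populations[[nm]]
    if (is.null(p$n) || p$n < 1L) stop("population ", nm, " needs n >= 1")
    if (abs(sum(p$freq) - 1) > 1e-9) {
      stop("frequency vector of ", nm, " must sum to 1")
    }
    if (is.null(names(p$freq)) || any(!nzchar(names(p$freq)))) {
      stop("frequency vector of ", nm, " must be named by haplogroup")
    }
  }
  if (!is.null(shared_fraction)) {
    stopifnot(shared_fraction >= 0, shared_fraction <= 1,
              length(populations) >= 2L)
  }
  structure(list(populations = populations, seed = as.integer(seed),
                 private_rate = private_rate,
                 heteroplasmy_prob = heteroplasmy_prob, window = window,
                 shared_fraction = shared_fraction),
            class = "sim_config")
}

# all rCRS positions used by any motif token of the tree
tree_motif_positions <- function(tree) {
  toks <- unlist(lapply(tree$nodes, `[[`, "motif"), use.names = FALSE)
  if (length(toks) == 0L) return(integer())
  sort(unique(as.integer(sub("^([0-9]+).*$", "\\1", toks))))
}

#' Demo population layout
#'
#' The packaged demo configuration mirrors the sampling design of a
#' country-wide Mongolian survey: 20 province groups plus an
#' `"unspecified"` group, sizes summing to 2,420, with eastern-Asian
#' haplogroups dominating everywhere and western-Eurasian ones enriched in
#' the westernmost provinces (about 22% overall).
#'
#' @param tree motif tree supplying the haplogroup names (default packaged).
#' @param scale multiply all sample sizes by this factor (sizes are kept
#'   >= 1); use e.g. `0.1` for a fast demo.
#' @return named list suitable for [sim_config()].
#' @export
demo_populations <- function(tree = load_packaged_tree(), scale = 1) {
  sizes <- c(
    Arkhangai = 4, Bayankhongor = 2, "Bayan-Olgii" = 216, Bulgan = 5,
    "Darkhan-Uul" = 1, Dornod = 370, Dornogovi = 26, Dundgovi = 1,
    "Govi-Altai" = 8, Khentii = 132, Khovd = 429, Khovsgol = 307,
    Omnogovi = 2, Ovorkhangai = 8, Selenge = 4, Sukhbaatar = 246,
    Tov = 10, Ulaanbaatar = 2, Uvs = 132, Zavkhan = 167, unspecified = 348)
  # WEu weight by rough west-to-east position of each group
  weu_weight <- c(
    Arkhangai = 0.20, Bayankhongor = 0.20, "Bayan-Olgii" = 0.45, Bulgan = 0.15,
    "Darkhan-Uul" = 0.15, Dornod = 0.10, Dornogovi = 0.12, Dundgovi = 0.12,
    "Govi-Altai" = 0.30, Khentii = 0.10, Khovd = 0.40, Khovsgol = 0.15,
    Omnogovi = 0.12, Ovorkhangai = 0.20, Selenge = 0.15, Sukhbaatar = 0.10,
    Tov = 0.15, Ulaanbaatar = 0.20, Uvs = 0.35, Zavkhan = 0.25,
    unspecified = 0.22)
  eas <- c(C4 = 0.24, Z1 = 0.03, D4 = 0.24, G2a = 0.08, M7b = 0.05,
           M9a = 0.04, A4 = 0.08, B4 = 0.08, N9a = 0.05, Y1 = 0.03,
           F1b = 0.06, R11 = 0.02)
  weu <- c(H1b = 0.13, H1c = 0.10, H1j = 0.05, H5a1 = 0.08, HV13b1 = 0.05,
           V1 = 0.04, J1b2 = 0.09, T2g1a = 0.08, U2e1b = 0.07, U4b1a4 = 0.08,
           U5a1 = 0.10, K1 = 0.06, I1c = 0.04, W1 = 0.02, X2b = 0.01)
  stopifnot(all(c(names(eas), names(weu)) %in% names(tree$nodes)))
  out <- lapply(names(sizes), function(nm) {
    w <- weu_weight[[nm]]
    list(n = max(1L, as.integer(round(sizes[[nm]] * scale))),
         freq = c(eas * (1 - w) / sum(eas), weu * w / sum(weu)))
  })
  names(out) <- names(sizes)
  out
}

#' Simulate a modern control-region dataset with known truth
#'
#' For each sample: draw a haplogroup from its population's frequency
#' vector; start from the reference window edited by the haplogroup's
#' cumulative motif; add `Poisson(private_rate)` private substitutions at
#' positions drawn uniformly from the window *outside* every motif-defining
#' site (keeping the generating haplogroup recoverable); with probability
#' `heteroplasmy_prob` replace one base with the two-base IUPAC code mixing
#' it with a random alternative. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @param tree motif tree (default packaged); every haplogroup named in a
#'   frequency vector must be one of its nodes.
#' @param reference an [mt_reference()] (default packaged synthetic).
#' @return list of class `mt_simulation`: `sequences` (named character),
#'   `populations` (data frame `sample_id`, `population`), `truth` (data
#'   frame `sample_id`, `population`, `haplogroup`, `haplotype_key`),
#'   `config`.
#' @export
simulate_modern <- function(config, tree = load_packaged_tree(),
                            reference = packaged_reference()) {
  stopifnot(inherits(config, "sim_config"))
  for (nm in names(config$populations)) {
    hg <- names(config$populations[[nm]]$freq)
    bad <- setdiff(hg, names(tree$nodes))
    if (length(bad)) {
      stop("frequency vector of ", nm, " names unknown haplogroup(s): ",
           paste(bad, collapse = ", "))
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  window <- config$window
  wpos <- window_positions(window)
  motif_pos <- tree_motif_positions(tree)
  free_pos <- setdiff(wpos, motif_pos)
  motifs <- lapply(stats::setNames(nm = names(tree$nodes)), function(n) {
    cumulative_motif(tree, n, window)
  })

  shared <- config$shared_fraction
  tag_iter <- 0L
  draw_sample <- function(pop_name, i, forced = NULL) {
    p <- config$populations[[pop_name]]
    if (is.null(forced)) {
      hg <- sample(names(p$freq), 1L, prob = p$freq)
      m <- motifs[[hg]]
      priv_n <- stats::rpois(1L, config$private_rate)
      priv_pos <- if (priv_n > 0L) sample(free_pos, min(priv_n, length(free_pos)))
                  else integer()
      if (!is.null(shared)) {
        tag_iter <<- tag_iter + 1L
        tag <- free_pos[length(free_pos) + 1L - tag_iter]  # unique per sample
        priv_pos <- union(setdiff(priv_pos, tag), tag)
      }
      priv_base <- vapply(priv_pos, function(pp) {
        sample(setdiff(c("A", "C", "G", "T"), ref_base(reference, pp)), 1L)
      }, "")
      core <- list(hg = hg,
                   position = c(m$position, priv_pos),
                   kind = c(m$kind, rep("sub", length(priv_pos))),
                   base = c(m$base, priv_base),
                   idx = c(m$ins_index, rep(NA_integer_, length(priv_pos))))
    } else core <- forced
    # heteroplasmy: overlay one IUPAC base on the realized sequence
    het <- NULL
    if (stats::runif(1L) < config$heteroplasmy_prob) {
      hp <- sample(wpos, 1L)
      cur <- if (hp %in% core$position[core$kind == "sub"]) {
        core$base[core$kind == "sub" & core$position == hp]
      } else ref_base(reference, hp)
      if (cur %in% c("A", "C", "G", "T")) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        code <- IUPAC2[[paste(sort(c(cur, alt)), collapse = "")]]
        het <- list(position = hp, code = code)
      }
    }
    list(core = core, het = het)
  }

  realize <- function(id, pop_name, s) {
    core <- s$core
    pos <- core$position; kind <- core$kind; base <- core$base; idx <- core$idx
    if (!is.null(s$het)) {
      hp <- s$het$position
      at <- which(kind == "sub" & pos == hp)
      if (length(at)) {
        base[at] <- s$het$code
      } else {
        pos <- c(pos, hp); kind <- c(kind, "sub")
        base <- c(base, s$het$code); idx <- c(idx, NA_integer_)
      }
    }
    vars <- variant_table(pos, kind, base, idx)
    prof <- haplotype_profile(id, pop_name, window, vars)
    seqstr <- profile_to_sequence(prof, reference)
    truth_key <- haplotype_key(mask_heteroplasmies(prof), window)
    list(sequence = seqstr, key = truth_key)
  }

  ids <- character(); pops <- character(); hgs <- character()
  keys <- character(); seqs <- character()
  pop_names <- names(config$populations)
  shared_bank <- list()
  n_first <- if (!is.null(shared)) config$populations[[pop_names[1L]]]$n else 0L
  n_second <- if (!is.null(shared)) config$populations[[pop_names[2L]]]$n else 0L
  n_shared <- if (!is.null(shared)) round(shared * min(n_first, n_second)) else 0L
  counter <- 0L
  for (pi in seq_along(pop_names)) {
    pop <- pop_names[pi]
    for (i in seq_len(config$populations[[pop]]$n)) {
      counter <- counter + 1L
      id <- sprintf("S%05d", counter)
      forced <- NULL
      if (!is.null(shared) && pi == 2L && i <= n_shared) {
        forced <- shared_bank[[i]]  # replicate haplotype planted in pop 1
      }
      s <- draw_sample(pop, i, forced = forced)
      if (!is.null(shared) && pi == 1L && i <= n_shared) {
        shared_bank[[i]] <- s$core
      }
      r <- realize(id, pop, s)
      ids <- c(ids, id); pops <- c(pops, pop); hgs <- c(hgs, s$core$hg)
      keys <- c(keys, r$key); seqs <- c(seqs, r$sequence)
    }
  }
  structure(list(
    sequences = stats::setNames(seqs, ids),
    populations = data.frame(sample_id = ids, population = pops,
                             stringsAsFactors = FALSE),
    truth = data.frame(sample_id = ids, population = pops, haplogroup = hgs,
                       haplotype_key = keys, stringsAsFactors = FALSE),
    config = config), class = "mt_simulation")
}

#' Write a simulation to disk
#' @param sim an [simulate_modern()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`fasta`, `popmap`, `truth`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "simulated.fasta")
  writeLines(paste0(">", names(sim$sequences), "\n", sim$sequences), fasta)
  popmap <- file.path(dir, "popmap.tsv")
  utils::write.table(sim$populations, popmap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, popmap = popmap, truth = truth))
}

#' Simulate an ancient-mitogenome metadata table with known trace truth
#'
#' Each scenario row plants one lineage trajectory: optionally a record
#' inside the longitude band (its haplogroup may be a sub-lineage of the
#' traced name) and optionally a western precursor record. The truth
#' status follows directly: no band record = `absent_in_band`; band record
#' dated at or before the cutoff = `pre_cutoff_presence`; later =
#' `post_cutoff_arrival`.
#'
#' @param scenarios data frame with columns `lineage`, `band_haplogroup`
#'   (optional, defaults to `lineage`), `band_lon`, `band_date_ce`,
#'   `band_lat`, `precursor_haplogroup` (optional), `precursor_lon`,
#'   `precursor_date_ce`, `precursor_lat`; use `NA` for absent records.
#' @param band,cutoff_ce the trace parameters the truth refers to.
#' @return list: `records` (data frame in [read_ancient_table()] layout)
#'   and `truth` (data frame `lineage`, `status`).
#' @export
simulate_ancient <- function(scenarios, band = c(85, 125), cutoff_ce = -1000) {
  if (band[1L] >= band[2L]) stop("band must satisfy lon_min < lon_max")
  if (nrow(scenarios) == 0L) {
    return(list(records = data.frame(record_id = character(),
                                     haplogroup = character(),
                                     date_ce = numeric(), longitude = numeric(),
                                     latitude = numeric(), site = character(),
                                     stringsAsFactors = FALSE),
                truth = data.frame(lineage = character(), status = character(),
                                   stringsAsFactors = FALSE)))
  }
  recs <- list(); truth <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    lineage <- sc$lineage
    status <- "absent_in_band"
    if (!is.na(sc$band_date_ce)) {
      if (sc$band_lon < band[1L] || sc$band_lon > band[2L]) {
        stop("band record for ", lineage, " lies outside the band")
      }
      hg <- if (!is.null(sc$band_haplogroup) && !is.na(sc$band_haplogroup))
        sc$band_haplogroup else lineage
      recs[[length(recs) + 1L]] <- data.frame(
        record_id = paste0("anc_", lineage, "_band"), haplogroup = hg,
        date_ce = sc$band_date_ce, longitude = sc$band_lon,
        latitude = if ("band_lat" %in% names(sc) && !is.na(sc$band_lat))
          sc$band_lat else 47, site = paste0("band_site_", lineage),
        stringsAsFactors = FALSE)
      status <- if (sc$band_date_ce <= cutoff_ce) "pre_cutoff_presence"
                else "post_cutoff_arrival"
    }
    if (!is.na(sc$precursor_date_ce)) {
      hg <- if (!is.null(sc$precursor_haplogroup) && !is.na(sc$precursor_haplogroup))
        sc$precursor_haplogroup else lineage
      recs[[length(recs) + 1L]] <- data.frame(
        record_id = paste0("anc_", lineage, "_west"), haplogroup = hg,
        date_ce = sc$precursor_date_ce, longitude = sc$precursor_lon,
        latitude = if ("precursor_lat" %in% names(sc) && !is.na(sc$precursor_lat))
          sc$precursor_lat else 45, site = paste0("west_site_", lineage),
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(lineage = lineage,
                                              status = status,
                                              stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' The packaged ancient-trace narrative scenario
#'
#' A synthetic stand-in for a curated ancient-mitogenome comparison table:
#' 13 western-Eurasian lineages planted to arrive in the 85-125 degrees E
#' band after 1000 BCE (six of them - H5a1, J1b2, T2g, U2e1b, U4b1a1a1,
#' U4b1a4 - with an earliest western precursor 20-40 degrees to the west,
#' the trade-route-consistent signature), plus seven lineages already
#' present before the cutoff. `lineages` lists the names to trace,
#' including `"T2g"`, whose in-band record belongs to its sub-lineage
#' T2g1a.
#'
#' @return list: `scenarios` (data frame for [simulate_ancient()]) and
#'   `lineages` (character vector to pass to [trace_report()]).
#' @export
default_ancient_scenario <- function() {
  sc <- function(lineage, band_hg, b_lon, b_date, p_hg, p_lon, p_date) {
    data.frame(lineage = lineage, band_haplogroup = band_hg,
               band_lon = b_lon, band_date_ce = b_date, band_lat = 47,
               precursor_haplogroup = p_hg, precursor_lon = p_lon,
               precursor_date_ce = p_date, precursor_lat = 45,
               stringsAsFactors = FALSE)
  }
  scenarios <- rbind(
    # post-cutoff, route-consistent (offset 20-40 degrees west, earlier date)
    sc("H5a1",     NA, 102, -480, NA, 72, -700),
    sc("J1b2",     NA, 100, -450, NA, 68, -800),
    sc("U2e1b",    NA, 108, -500, NA, 75, -650),
    sc("U4b1a1a1", NA,  95, -520, NA, 62, -900),
    sc("U4b1a4",   NA, 110, -400, NA, 78, -600),
    # the in-band record is the sub-lineage T2g1a; tracing "T2g" picks it up
    # together with the western T2g precursor (route-consistent), while
    # tracing "T2g1a" finds no matching precursor (post-cutoff only)
    sc("T2g",   "T2g1a", 104, -430, "T2g", 73, -750),
    # post-cutoff, not route-consistent (precursor too far west or absent)
    sc("I1c",      NA, 101, -300, NA, 46, -1200),
    sc("J1b1b1",   NA, 103,  400, NA, 48, -300),
    sc("J1d6",     NA,  97, -200, NA, NA, NA),
    sc("U2e1a1",   NA, 105,  300, NA, 50, -100),
    sc("U4d2",     NA,  99, -350, NA, 44, -1100),
    sc("U5b1c2",   NA, 106, -250, NA, NA, NA),
    sc("U8b1a1",   NA,  92, -480, NA, 30, -1500),
    # pre-cutoff presences
    sc("U5a1",     NA, 101, -3000, NA, 60, -3500),
    sc("H1b",      NA,  90, -1500, NA, NA, NA),
    sc("H1c",      NA,  93, -1800, NA, NA, NA),
    sc("H1j",      NA,  96, -1300, NA, NA, NA),
    sc("K1",       NA, 100, -2500, NA, NA, NA),
    sc("T1a",      NA,  94, -1600, NA, NA, NA),
    sc("I4",       NA,  98, -2000, NA, NA, NA))
  lineages <- c("H5a1", "I1c", "J1b1b1", "J1b2", "J1d6", "T2g1a", "U2e1a1",
                "U2e1b", "U4b1a1a1", "U4b1a4", "U4d2", "U5b1c2", "U8b1a1",
                "T2g", "U5a1", "H1b", "H1c", "H1j", "K1", "T1a", "I4")
  list(scenarios = scenarios, lineages = lineages)
}
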