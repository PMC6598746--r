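# Synthetic multi-locus datasets with planted ground truth: two type
# radiations sampled at a reef site, a slow organellar marker, an
# intragenomically variable nuclear marker, a hypervariable organellar
# marker with an indel block, planted hybrids, confounders, and NGS-style
# read-count tables (hybridisation vs incomplete-lineage-sorting
# scenarios).

#' Parameters of the synthetic multi-locus generator
#'
#' Defaults emulate the empirical setting the workflow targets: three
#' markers of 787 (slow organellar, near-invariant), 369 (nuclear,
#' ribosomal-spacer-like) and 531 (hypervariable organellar, non-coding)
#' columns; two type radiations; sister types separated by a handful of
#' diagnostic columns (4 at the nuclear marker); radiations separated by
#' ~2 columns at the slow marker and 64 at the hypervariable one,
#' including a 49-column deletion block private to the second radiation.
#'
#' @param locus_lengths named lengths of the three loci.
#' @param roles organellar/nuclear role per locus.
#' @param types_per_radiation sequence types in each of the two radiations.
#' @param samples_per_type samples drawn per type.
#' @param between_radiation substitutions separating the radiation
#'   ancestors, per locus (the hypervariable count includes the deletion).
#' @param between_type substitutions separating a type from its radiation
#'   ancestor, per locus.
#' @param deletion_length contiguous gap block private to radiation B at
#'   the hypervariable locus (counted inside its between-radiation total).
#' @param within_type expected private (autapomorphic) mutations per
#'   sample, per locus (Poisson means).
#' @param n_hybrids planted hybrids (nuclear sequence from a donor type in
#'   the other radiation, organellar sequences from the recipient type).
#' @param n_divergent_chloroplast confounder samples with a hyper-divergent
#'   hypervariable-organellar sequence.
#' @param n_autapomorphic confounder samples carrying extra
#'   parsimony-uninformative singleton mutations at the nuclear locus.
#' @param divergent_fraction fraction of columns mutated in the
#'   divergent-chloroplast confounder.
#' @param n_extra_autapomorphies singletons added per autapomorphy
#'   confounder.
#' @param prefix sample-id prefix.
#' @export
sim_params <- function(locus_lengths = c(cob = 787, its2 = 369, psba = 531),
                       roles = c(cob = "organellar", its2 = "nuclear",
                                 psba = "organellar"),
                       types_per_radiation = 2,
                       samples_per_type = 5,
                       between_radiation = c(cob = 2, its2 = 8, psba = 64),
                       between_type = c(cob = 0, its2 = 4, psba = 8),
                       deletion_length = 49,
                       within_type = c(cob = 0.05, its2 = 0.15, psba = 0.5),
                       n_hybrids = 1,
                       n_divergent_chloroplast = 0,
                       n_autapomorphic = 0,
                       divergent_fraction = 0.2,
                       n_extra_autapomorphies = 3,
                       prefix = "SIM") {
  list(locus_lengths = locus_lengths, roles = roles,
       types_per_radiation = types_per_radiation,
       samples_per_type = samples_per_type,
       between_radiation = between_radiation, between_type = between_type,
       deletion_length = deletion_length, within_type = within_type,
       n_hybrids = n_hybrids,
       n_divergent_chloroplast = n_divergent_chloroplast,
       n_autapomorphic = n_autapomorphic,
       divergent_fraction = divergent_fraction,
       n_extra_autapomorphies = n_extra_autapomorphies,
       prefix = prefix)
}

BASES <- c("A", "C", "G", "T")

mutate_positions <- function(seq, k, allowed = NULL) {
  if (k <= 0) return(seq)
  if (is.null(allowed)) allowed <- which(seq != "-")
  k <- min(k, length(allowed))
  pos <- sample(allowed, k)
  for (p in pos) {
    seq[p] <- sample(setdiff(BASES, seq[p]), 1)
  }
  seq
}

#' Simulate a multi-locus dataset with planted hybrids and confounders
#'
#' Type consensus sequences are evolved along a fixed two-radiation type
#' tree per locus (both organellar loci share one history by
#' construction); samples copy their type consensus plus Poisson-distributed
#' private mutations; hybrids copy the nuclear consensus of a donor type in
#' the opposite radiation while keeping the recipient type's organellar
#' sequences; confounders are injected on request. Deterministic given the
#' seed.
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed.
#' @return list with `alignments` (named list of [locus_alignment]s),
#'   `truth` (data.frame: per-sample type per locus, hybrid flag and donor
#'   types, confounder label), and `params`.
#' @export
simulate_multilocus_dataset <- function(params = sim_params(), seed = 1L) {
  set.seed(derive_seed(seed, 9001L))
  loci <- names(params$locus_lengths)
  npr <- params$types_per_radiation
  type_names <- c(paste0("C1.", seq_len(npr)), paste0("C3.", seq_len(npr)))
  radiation <- rep(c("A", "B"), each = npr)
  names(radiation) <- type_names

  # per-locus type consensus sequences
  consensus <- list()
  for (loc in loci) {
    L <- params$locus_lengths[[loc]]
    root <- sample(BASES, L, replace = TRUE)
    d_rad <- params$between_radiation[[loc]]
    radA <- root
    radB <- root
    gap_cols <- integer(0)
    if (loc == "psba" && params$deletion_length > 0) {
      start <- sample(seq_len(L - params$deletion_length), 1)
      gap_cols <- start:(start + params$deletion_length - 1)
      radB[gap_cols] <- "-"
      d_rad <- max(0, d_rad - params$deletion_length)
    }
    radB <- mutate_positions(radB, d_rad, setdiff(which(radB != "-"), gap_cols))
    cons <- list()
    for (ty in type_names) {
      anc <- if (radiation[ty] == "A") radA else radB
      cons[[ty]] <- mutate_positions(anc, params$between_type[[loc]])
    }
    consensus[[loc]] <- cons
  }

  nuc <- names(params$roles)[params$roles == "nuclear"][1]
  org <- names(params$roles)[params$roles == "organellar"]
  ids <- character(0)
  truth <- list()
  seqs <- lapply(loci, function(l) list())
  names(seqs) <- loci
  counter <- 0L
  add_sample <- function(types_by_locus, is_hybrid = FALSE,
                         nuclear_donor = NA, organellar_donor = NA,
                         confounder = "none") {
    counter <<- counter + 1L
    id <- sprintf("%s%03d", params$prefix, counter)
    ids <<- c(ids, id)
    for (loc in loci) {
      s <- consensus[[loc]][[types_by_locus[[loc]]]]
      s <- mutate_positions(s, rpois(1, params$within_type[[loc]]))
      seqs[[loc]][[id]] <<- s
    }
    row <- data.frame(sample_id = id, is_hybrid = is_hybrid,
                      nuclear_donor = nuclear_donor,
                      organellar_donor = organellar_donor,
                      confounder = confounder,
                      nuclear_type = types_by_locus[[nuc]],
                      stringsAsFactors = FALSE)
    for (loc in loci) row[[paste0("type_", loc)]] <- types_by_locus[[loc]]
    truth[[length(truth) + 1]] <<- row
    id
  }

  for (ty in type_names) {
    for (k in seq_len(params$samples_per_type)) {
      add_sample(setNames(as.list(rep(ty, length(loci))), loci))
    }
  }

  typesA <- type_names[radiation == "A"]
  typesB <- type_names[radiation == "B"]
  if (params$n_hybrids > 0) {
    for (h in seq_len(params$n_hybrids)) {
      recipient <- typesA[1 + (h - 1) %% length(typesA)]
      donor <- typesB[1 + (h - 1) %% length(typesB)]
      tb <- setNames(as.list(rep(recipient, length(loci))), loci)
      tb[[nuc]] <- donor
      add_sample(tb, is_hybrid = TRUE, nuclear_donor = donor,
                 organellar_donor = recipient, confounder = "none")
    }
  }
  if (params$n_divergent_chloroplast > 0) {
    for (k in seq_len(params$n_divergent_chloroplast)) {
      ty <- typesA[1 + (k - 1) %% length(typesA)]
      id <- add_sample(setNames(as.list(rep(ty, length(loci))), loci),
                       confounder = "divergent_chloroplast")
      s <- seqs[["psba"]][[id]]
      seqs[["psba"]][[id]] <- mutate_positions(
        s, round(params$divergent_fraction * length(s)))
    }
  }
  if (params$n_autapomorphic > 0) {
    for (k in seq_len(params$n_autapomorphic)) {
      ty <- typesB[1 + (k - 1) %% length(typesB)]
      id <- add_sample(setNames(as.list(rep(ty, length(loci))), loci),
                       confounder = "autapomorphies")
      seqs[[nuc]][[id]] <- mutate_positions(seqs[[nuc]][[id]],
                                            params$n_extra_autapomorphies)
    }
  }

  alignments <- lapply(loci, function(loc) {
    m <- do.call(rbind, seqs[[loc]][ids])
    rownames(m) <- ids
    locus_alignment(m, loc)
  })
  names(alignments) <- loci
  truth <- do.call(rbind, truth)
  list(alignments = alignments, truth = truth, params = params,
       consensus = consensus, radiation = radiation)
}

#' Simulate an NGS read-count table consistent with a dataset's truth
#'
#' Multinomial read counts per sample: the dominant variant is the
#' sample's nuclear type; the remaining mass is spread over generic
#' background variants, with an optional counterpart-variant weight (zero
#' by default, the pure-parental-population pattern expected under
#' hybridisation rather than incomplete lineage sorting).
#'
#' @param truth truth data.frame from [simulate_multilocus_dataset()].
#' @param total_reads reads per sample.
#' @param dominant_fraction expected share of the dominant variant.
#' @param counterpart_weight expected share (of total) of the counterpart
#'   nuclear variant from the opposite radiation.
#' @param seed integer seed.
#' @return a `read_count_table`.
#' @export
simulate_read_counts <- function(truth, total_reads = 20000,
                                 dominant_fraction = 0.95,
                                 counterpart_weight = 0, seed = 1L) {
  set.seed(derive_seed(seed, 9002L))
  nuclear_types <- sort(unique(truth$nuclear_type))
  bg <- paste0("bg", 1:3)
  variants <- c(nuclear_types, bg)
  m <- matrix(0, nrow(truth), length(variants),
              dimnames = list(truth$sample_id, variants))
  for (i in seq_len(nrow(truth))) {
    dom <- truth$nuclear_type[i]
    counterpart <- counterpart_of(dom, nuclear_types)
    w <- setNames(rep(0, length(variants)), variants)
    w[dom] <- dominant_fraction
    w[counterpart] <- counterpart_weight
    w[bg] <- (1 - sum(w)) / length(bg)
    m[i, ] <- rmultinom(1, total_reads, w)
  }
  structure(m, class = c("read_count_table", "matrix"))
}

# the "other radiation" nuclear variant: types are labelled C1.x / C3.x
counterpart_of <- function(type, nuclear_types) {
  rad <- substr(type, 1, 2)
  other <- nuclear_types[substr(nuclear_types, 1, 2) != rad]
  if (!length(other)) return(type)
  other[1]
}

#' Simulate an incomplete-lineage-sorting scenario
#'
#' One focal type retains an ancestral nuclear polymorphism: every member
#' carries BOTH its own nuclear variant and the counterpart variant from
#' the other radiation intragenomically (ratios vary per sample), and a
#' configurable number of members are dominance-switched so their dominant
#' (alignment) nuclear sequence is the counterpart. Organellar loci stay
#' uniform. The read-count table reflects the intragenomic ratios, which
#' is what distinguishes this scenario from hybridisation.
#'
#' @param params a [sim_params()] (hybrids are forced off).
#' @param seed integer seed.
#' @param ancestral_fraction_range intragenomic counterpart share in
#'   affected, non-switched samples.
#' @param n_switched dominance-switched samples in the affected type.
#' @param switched_fraction_range intragenomic counterpart share in
#'   switched samples.
#' @param total_reads reads per sample.
#' @return list with `alignments`, `read_counts`, `truth`, `params`.
#' @export
simulate_ils_dataset <- function(params = sim_params(), seed = 1L,
                                 ancestral_fraction_range = c(0.1, 0.4),
                                 n_switched = 1,
                                 switched_fraction_range = c(0.55, 0.8),
                                 total_reads = 20000) {
  params$n_hybrids <- 0
  ds <- simulate_multilocus_dataset(params, seed)
  set.seed(derive_seed(seed, 9003L))
  truth <- ds$truth
  nuclear_types <- sort(unique(truth$nuclear_type))
  nuc <- names(params$roles)[params$roles == "nuclear"][1]
  affected_type <- type_of_radiation(nuclear_types, "C1")[1]
  counterpart <- counterpart_of(affected_type, nuclear_types)
  members <- truth$sample_id[truth$nuclear_type == affected_type]
  switched <- sample(members, min(n_switched, length(members)))

  rc <- simulate_read_counts(truth, total_reads = total_reads, seed = seed)
  rc <- unclass(rc)
  for (id in members) {
    frac <- if (id %in% switched) runif(1, switched_fraction_range[1],
                                        switched_fraction_range[2])
    else runif(1, ancestral_fraction_range[1], ancestral_fraction_range[2])
    w <- setNames(rep(0, ncol(rc)), colnames(rc))
    w[counterpart] <- frac
    w[affected_type] <- 0.95 - frac
    w[paste0("bg", 1:3)] <- 0.05 / 3
    rc[id, ] <- rmultinom(1, total_reads, w)
  }
  # dominance-switched samples present the counterpart as their dominant
  # (alignment) nuclear sequence
  aln <- ds$alignments
  for (id in switched) {
    aln[[nuc]]$matrix[id, ] <- ds$consensus[[nuc]][[counterpart]]
    truth$nuclear_type[truth$sample_id == id] <- counterpart
  }
  truth$ils_affected <- truth$sample_id %in% members
  truth$ils_switched <- truth$sample_id %in% switched
  list(alignments = aln, read_counts = structure(
    rc, class = c("read_count_table", "matrix")),
    truth = truth, params = params)
}

type_of_radiation <- function(types, rad_prefix) {
  types[substr(types, 1, 2) == rad_prefix]
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' FASTA per locus, CSV read counts (when present), JSON truth.
#' @param dataset result of [simulate_multilocus_dataset()] or
#'   [simulate_ils_dataset()].
#' @param dir output directory (created).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (loc in names(dataset$alignments)) {
    write_alignment_fasta(dataset$alignments[[loc]],
                          file.path(dir, paste0(loc, ".fasta")))
  }
  if (!is.null(dataset$read_counts)) {
    write_count_table(dataset$read_counts, file.path(dir, "read_counts.csv"))
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
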