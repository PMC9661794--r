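# Synthetic multi-species fixtures with recorded ground truth. The genome
# generator emits gene models (GFF3), domain-hit tables, coiled-coil score
# tracks, 12-column similarity hits and MCScanX-style collinearity in
# exactly the dialects core_io reads, plus a TruthSet of planted
# architectures, homolog relations and lineages. The expression generator
# emits a two-condition count matrix with planted up-regulated genes and
# correlated module blocks.

# per-file pseudo-random substream: a fixed function of the master seed and
# a stage index, so adding a new output never perturbs existing fixtures
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 10007 + k) %% 2147483647L
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate a three-species Dendrobium-like design: 19 chromosomes
#' per species, a focal species whose planted type table matches a typical
#' orchid NBS survey column (22 NBS-LRR + 52 non-NBS-LRR genes), complete
#' and degenerate orthologous lineages, planted type changes, and both
#' same- and different-chromosome duplications.
#'
#' @param species ordered species chain (first = reference for chromosome
#'   lineages).
#' @param n_chromosomes chromosomes per species.
#' @param type_counts named integer vector: planted architecture type ->
#'   gene count, applied to every species' background gene pool.
#' @param focal_species species whose lineage members are drawn from its
#'   background pool so its type table stays exactly \code{type_counts}.
#' @param n_lineages_complete lineages with a member in every species.
#' @param n_lineages_incomplete lineages missing the last species' member
#'   (planted degeneration by gene loss).
#' @param n_type_changed complete lineages whose last member carries a
#'   changed architecture type.
#' @param n_nbarc_deleted complete lineages whose last member loses its
#'   NB-ARC hit (domain-level degeneration; also changes its truth type).
#' @param n_chromosome_lineages distinct reference chromosomes the lineages
#'   are planted on.
#' @param n_dup_homo,n_dup_hetero same-/different-chromosome duplication
#'   pairs planted in the focal species.
#' @param block_fill filler (non-NBS) gene pairs added per collinear block
#'   so the chromosome correspondence has a clear majority.
#' @param noise_frac fraction of genes receiving an extra insignificant
#'   domain hit (above the e-value cutoff; exercises filtering). 0 = the
#'   noiseless mode in which recovery is exact.
#' @return a list of class \code{genome_config}.
#' @export
genomeConfig <- function(species = c("spcA", "spcB", "spcC"),
                         n_chromosomes = 19,
                         type_counts = c(CNL = 10, CNLCN = 1, NL = 9,
                                         NLNL = 1, NLNNL = 1,
                                         CN = 24, CNC = 1, N = 27),
                         focal_species = species[2],
                         n_lineages_complete = 10,
                         n_lineages_incomplete = 4,
                         n_type_changed = 3,
                         n_nbarc_deleted = 1,
                         n_chromosome_lineages = 13,
                         n_dup_homo = 3,
                         n_dup_hetero = 2,
                         block_fill = 5,
                         noise_frac = 0.1) {
  cfg <- as.list(environment())
  stopifnot(length(species) >= 2, focal_species %in% species,
            n_type_changed <= n_lineages_complete,
            n_nbarc_deleted <= n_lineages_complete - n_type_changed,
            n_chromosome_lineages <= n_chromosomes)
  n_lin <- n_lineages_complete + n_lineages_incomplete
  nbs_pool <- sum(type_counts[grepl("N", names(type_counts))])
  if (n_lin > nbs_pool)
    stop("infeasible config: more planted lineages (", n_lin,
         ") than NBS genes in the focal pool (", nbs_pool, ")")
  structure(cfg, class = "genome_config")
}

#' Preset genome configuration shaped like the six-orchid survey
#'
#' Three Dendrobium-like species, 19 chromosomes, focal-species type table
#' with 22 NBS-LRR and 52 non-NBS-LRR genes.
#' @return a \code{genome_config}.
#' @export
orchidPresetConfig <- function() genomeConfig()

# change a type for the planted type-change lineages: toggle a leading C,
# which preserves the N (the gene stays an NBS gene) but renames the type
changeType <- function(t) {
  if (startsWith(t, "C") && nchar(t) > 1) substring(t, 2) else paste0("C", t)
}

# drop every N from a type string (NB-ARC degeneration)
dropN <- function(t) {
  out <- gsub("N", "", t)
  if (nchar(out) == 0) stop("cannot delete NB-ARC from a bare-N gene")
  out
}

# residue layout for one architecture string: returns data.frame of hit
# rows (accession-level, LRRs as clustered repeats) and the coil segments
layoutDomains <- function(letters) {
  pos <- 51L
  hit_rows <- list(); coil_segs <- list()
  for (l in letters) {
    if (l == "N") {
      w <- sample(150:300, 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        data.frame(acc = "PF00931", start = pos, end = pos + w - 1L)
      pos <- pos + w - 1L
    } else if (l == "T") {
      w <- sample(120:180, 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        data.frame(acc = "PF01582", start = pos, end = pos + w - 1L)
      pos <- pos + w - 1L
    } else if (l == "R") {
      w <- sample(100:150, 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        data.frame(acc = "PF05659", start = pos, end = pos + w - 1L)
      pos <- pos + w - 1L
    } else if (l == "L") {
      # clustered LRR repeats: 2-4 short hits separated by small gaps
      k <- sample(2:4, 1)
      for (j in seq_len(k)) {
        w <- sample(25:60, 1)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          acc = sample(c("PF00560", "PF13855", "PF12799", "PF13306"), 1),
          start = pos, end = pos + w - 1L)
        pos <- pos + w - 1L
        if (j < k) pos <- pos + sample(10:100, 1)
      }
    } else if (l == "C") {
      w <- sample(21:40, 1)
      coil_segs[[length(coil_segs) + 1L]] <- c(pos, pos + w - 1L)
      pos <- pos + w - 1L
    }
    pos <- pos + sample(180L:260L, 1)  # inter-unit gap > merge gap_max
  }
  list(hits = if (length(hit_rows)) do.call(rbind, hit_rows) else NULL,
       coils = coil_segs, protein_length = pos + 30L)
}

#' Generate a synthetic multi-species genome fixture
#'
#' Writes gene models, domain hits, coiled-coil tracks, similarity hits and
#' collinearity files for the configured species, with planted
#' architectures, orthologous lineages (complete, degenerate and
#' type-changed), duplications and collinear blocks; returns the file
#' paths, the parsed-equivalent tables and the TruthSet. The same seed
#' yields byte-identical files.
#'
#' @param config a [genomeConfig()] list.
#' @param seed master seed; every output file uses its own substream.
#' @param out_dir output directory (created); default a fresh tempdir.
#' @return list with \code{files} (named paths), \code{truth} (planted
#'   architectures, relations, lineage members and flags, seed) and
#'   \code{tables} (the in-memory gene models).
#' @export
generateGenomes <- function(config = genomeConfig(), seed = 1,
                            out_dir = tempfile("nbssim")) {
  stopifnot(inherits(config, "genome_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- config$species
  n_sp <- length(sp)
  chrom_names <- function(s) sprintf("%s_chr%02d", s, seq_len(config$n_chromosomes))

  # --- stage 1: plan genes and lineages (stream 1) -----------------------
  set.seed(subSeed(seed, 1))
  # chromosome permutations: species i chromosome perm[[i]][c] corresponds
  # to reference chromosome c
  perm <- vector("list", n_sp)
  perm[[1]] <- seq_len(config$n_chromosomes)
  for (i in seq_len(n_sp)[-1]) perm[[i]] <- sample(config$n_chromosomes)

  genes <- list()   # accumulating gene records
  arch <- list()    # truth architectures
  add_gene <- function(gene_id, species, ref_chr, type_name) {
    i <- match(species, sp)
    chr <- chrom_names(species)[perm[[i]][ref_chr]]
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gene_id, species = species, chromosome = chr,
      ref_chr = ref_chr, type_name = type_name, stringsAsFactors = FALSE)
  }

  # background pools: every species gets type_counts genes
  tc <- config$type_counts
  pool <- list()
  for (s in sp) {
    idx <- 0L
    for (t in names(tc)) {
      for (j in seq_len(tc[[t]])) {
        idx <- idx + 1L
        gid <- sprintf("%s_g%04d", s, idx)
        add_gene(gid, s, sample(config$n_chromosomes, 1), t)
        pool[[length(pool) + 1L]] <- data.frame(
          gene_id = gid, species = s, type_name = t,
          stringsAsFactors = FALSE)
      }
    }
  }
  pool <- do.call(rbind, pool)

  if (is.null(pool)) {
    # degenerate zero-gene config: emit empty but well-formed files
    files <- c(gff = file.path(out_dir, "genes.gff3"),
               domain_hits = file.path(out_dir, "domain_hits.tsv"),
               coil_tracks = file.path(out_dir, "coil_tracks.tsv"),
               similarity = file.path(out_dir, "similarity.tsv"),
               collinearity = file.path(out_dir, "collinearity.txt"),
               species_tree = file.path(out_dir, "species.nwk"))
    gm0 <- data.frame(gene_id = character(), species = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      exon_count = integer(), gene_length = integer(),
                      stringsAsFactors = FALSE)
    blocks0 <- data.frame(block_id = character(), species_a = character(),
                          species_b = character(), chr_a = character(),
                          chr_b = character(), gene_a = character(),
                          gene_b = character(), stringsAsFactors = FALSE)
    sims0 <- data.frame(query_id = character(), subject_id = character(),
                        percent_identity = numeric(),
                        alignment_length = integer(), evalue = numeric(),
                        bitscore = numeric(), stringsAsFactors = FALSE)
    writeGeneModels(gm0, files[["gff"]])
    writeDomainHits(emptyDomainHits(), files[["domain_hits"]])
    writeCoilTracks(list(), files[["coil_tracks"]])
    writeSimilarityHits(sims0, files[["similarity"]])
    writeCollinearity(blocks0, files[["collinearity"]])
    writeLines(paste0("(", paste(sp, collapse = ","), ");"),
               files[["species_tree"]])
    truth <- list(architectures = data.frame(), relations = data.frame(),
                  lineage_members = data.frame(),
                  lineage_flags = data.frame(), seed = seed,
                  config = config)
    return(list(files = files, truth = truth,
                tables = list(gene_models = gm0, blocks = blocks0,
                              similarity = sims0)))
  }

  # lineages: anchors are focal-species NBS background genes
  n_lin <- config$n_lineages_complete + config$n_lineages_incomplete
  focal_nbs <- pool[pool$species == config$focal_species &
                      grepl("N", pool$type_name), , drop = FALSE]
  # spread anchor types: round-robin over the distinct NBS types
  focal_nbs <- focal_nbs[order(match(focal_nbs$type_name,
                                     unique(focal_nbs$type_name)),
                               focal_nbs$gene_id), , drop = FALSE]
  by_type <- split(seq_len(nrow(focal_nbs)), focal_nbs$type_name)
  by_type <- by_type[unique(focal_nbs$type_name)]
  take <- integer(0)
  while (length(take) < n_lin) {
    for (t in names(by_type)) {
      if (length(take) >= n_lin) break
      left <- setdiff(by_type[[t]], take)
      if (length(left) > 0) take <- c(take, left[1])
    }
  }
  anchors <- focal_nbs[take, , drop = FALSE]

  lin_chr <- rep(seq_len(config$n_chromosome_lineages), length.out = n_lin)
  changed <- seq_len(config$n_type_changed)
  ndel <- if (config$n_nbarc_deleted > 0)
    config$n_type_changed + seq_len(config$n_nbarc_deleted) else integer(0)
  # avoid deleting N from a bare-N lineage type
  incomplete <- n_lin - seq_len(config$n_lineages_incomplete) + 1L

  gm_df <- do.call(rbind, genes)
  # re-plant anchor genes on their lineage chromosome
  focal_i <- match(config$focal_species, sp)
  lin_members <- list(); lin_flags <- list()
  relations <- list()
  for (k in seq_len(n_lin)) {
    lid <- sprintf("plin_%02d", k)
    base_type <- anchors$type_name[k]
    anchor_gene <- anchors$gene_id[k]
    rc <- lin_chr[k]
    gm_df$chromosome[gm_df$gene_id == anchor_gene] <-
      chrom_names(config$focal_species)[perm[[focal_i]][rc]]
    gm_df$ref_chr[gm_df$gene_id == anchor_gene] <- rc
    member_species <- if (k %in% incomplete) sp[-n_sp] else sp
    mem <- data.frame(gene_id = character(), species = character(),
                      type_name = character(), stringsAsFactors = FALSE)
    for (s in member_species) {
      if (s == config$focal_species) {
        gid <- anchor_gene; ty <- base_type
      } else {
        gid <- sprintf("%s_lin%02d", s, k)
        ty <- base_type
        is_last <- s == sp[n_sp]
        if (is_last && k %in% changed) ty <- changeType(ty)
        if (is_last && k %in% ndel && grepl("[^N]", ty)) ty <- dropN(ty)
        genes_row <- data.frame(
          gene_id = gid, species = s,
          chromosome = chrom_names(s)[perm[[match(s, sp)]][rc]],
          ref_chr = rc, type_name = ty, stringsAsFactors = FALSE)
        gm_df <- rbind(gm_df, genes_row)
      }
      mem <- rbind(mem, data.frame(gene_id = gid, species = s,
                                   type_name = ty,
                                   stringsAsFactors = FALSE))
    }
    # ortholog relations along adjacent species of the chain
    msp <- match(mem$species, sp)
    mem <- mem[order(msp), , drop = FALSE]
    for (j in seq_len(nrow(mem) - 1L))
      relations[[length(relations) + 1L]] <- data.frame(
        gene_a = mem$gene_id[j], gene_b = mem$gene_id[j + 1L],
        relation = "ortholog", lineage_id = lid, stringsAsFactors = FALSE)
    lin_members[[k]] <- data.frame(lineage_id = lid,
                                   species = mem$species,
                                   gene_id = mem$gene_id,
                                   type_name = mem$type_name,
                                   stringsAsFactors = FALSE)
    lin_flags[[k]] <- data.frame(
      lineage_id = lid, complete = length(member_species) == n_sp,
      type_conserved = length(unique(mem$type_name)) == 1,
      chromosome_lineage = chrom_names(sp[1])[rc],
      stringsAsFactors = FALSE)
  }

  # duplications in the focal species: pair up same-type background genes
  # (no new genes, so the focal type table stays exactly type_counts) and
  # place the pair on one chromosome (homochromosomal) or two
  dup_pool <- pool[pool$species == config$focal_species &
                     !pool$gene_id %in% anchors$gene_id, , drop = FALSE]
  dup_pool <- dup_pool[order(match(dup_pool$type_name, names(tc)),
                             dup_pool$gene_id), , drop = FALSE]
  cnt_by_type <- table(dup_pool$type_name)
  pairable <- names(cnt_by_type)[cnt_by_type >= 2]
  n_dup <- config$n_dup_homo + config$n_dup_hetero
  used <- character(0)
  for (d in seq_len(n_dup)) {
    avail <- dup_pool[!dup_pool$gene_id %in% used &
                        dup_pool$type_name %in% pairable, , drop = FALSE]
    ty_ok <- names(which(table(avail$type_name) >= 2))
    if (length(ty_ok) == 0)
      stop("infeasible config: not enough same-type genes for duplications")
    pick <- avail[avail$type_name == ty_ok[1], ][1:2, ]
    used <- c(used, pick$gene_id)
    homo <- d <= config$n_dup_homo
    i1 <- which(gm_df$gene_id == pick$gene_id[1])
    i2 <- which(gm_df$gene_id == pick$gene_id[2])
    rc1 <- gm_df$ref_chr[i1]
    rc2 <- if (homo) rc1 else
      ((rc1 + 2L) %% config$n_chromosomes) + 1L
    gm_df$ref_chr[i2] <- rc2
    gm_df$chromosome[i2] <-
      chrom_names(config$focal_species)[perm[[focal_i]][rc2]]
    relations[[length(relations) + 1L]] <- data.frame(
      gene_a = pick$gene_id[1], gene_b = pick$gene_id[2],
      relation = if (homo) "homochromosomal_duplication" else
        "heterochromosomal_duplication",
      lineage_id = NA_character_, stringsAsFactors = FALSE)
  }

  relations <- if (length(relations)) do.call(rbind, relations) else
    data.frame(gene_a = character(), gene_b = character(),
               relation = character(), lineage_id = character())

  # filler genes for collinear blocks: block per adjacent species pair and
  # reference chromosome used by any lineage
  fillers <- list(); blocks <- list()
  used_rc <- sort(unique(lin_chr))
  bnum <- 0L
  for (i in seq_len(n_sp - 1L)) {
    s1 <- sp[i]; s2 <- sp[i + 1L]
    for (rc in used_rc) {
      bnum <- bnum + 1L
      c1 <- chrom_names(s1)[perm[[i]][rc]]
      c2 <- chrom_names(s2)[perm[[i + 1L]][rc]]
      prs <- list()
      for (f in seq_len(config$block_fill)) {
        f1 <- sprintf("%s_fill%03d", s1, bnum * 10L + f)
        f2 <- sprintf("%s_fill%03d", s2, bnum * 10L + f)
        fillers[[length(fillers) + 1L]] <- data.frame(
          gene_id = c(f1, f2), species = c(s1, s2),
          chromosome = c(c1, c2), ref_chr = rc,
          type_name = NA_character_, stringsAsFactors = FALSE)
        prs[[length(prs) + 1L]] <- c(f1, f2)
      }
      # lineage pairs on this chromosome and species pair
      for (k in which(lin_chr == rc)) {
        mm <- lin_members[[k]]
        g1 <- mm$gene_id[mm$species == s1]
        g2 <- mm$gene_id[mm$species == s2]
        if (length(g1) == 1 && length(g2) == 1)
          prs[[length(prs) + 1L]] <- c(g1, g2)
      }
      pm <- do.call(rbind, prs)
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = paste0("block_", bnum), species_a = s1, species_b = s2,
        chr_a = c1, chr_b = c2, gene_a = pm[, 1], gene_b = pm[, 2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(fillers) > 0) gm_df <- rbind(gm_df, do.call(rbind, fillers))
  blocks <- do.call(rbind, blocks)

  # --- stage 2: gene models (stream 2) -----------------------------------
  set.seed(subSeed(seed, 2))
  n_g <- nrow(gm_df)
  exon_count <- sample(1:11, n_g, replace = TRUE,
                       prob = c(8, 4, 3, 2, 2, 1, 1, 1, 1, 1, 1))
  # gene length grows with exon count (exons + introns), giving the
  # positive exon-count/length correlation seen in real NBS surveys
  gene_length <- as.integer(round(
    exon_count * stats::runif(n_g, 400, 700) +
      pmax(exon_count - 1, 0) * stats::runif(n_g, 1500, 9000) +
      stats::runif(n_g, 500, 1500)))
  start <- integer(n_g)
  for (chr in unique(gm_df$chromosome)) {
    ci <- which(gm_df$chromosome == chr)
    gaps <- as.integer(round(stats::runif(length(ci), 5e3, 5e4)))
    start[ci] <- cumsum(gaps + c(0L, gene_length[ci][-length(ci)]))
  }
  gm_out <- data.frame(gene_id = gm_df$gene_id, species = gm_df$species,
                       chromosome = gm_df$chromosome, start = start,
                       end = start + gene_length - 1L,
                       strand = sample(c("+", "-"), n_g, replace = TRUE),
                       exon_count = exon_count, gene_length = gene_length,
                       stringsAsFactors = FALSE)
  gm_out <- gm_out[order(gm_out$species, gm_out$chromosome, gm_out$start), ]
  rownames(gm_out) <- NULL

  # --- stage 3: domain hits and coil tracks (stream 3) -------------------
  set.seed(subSeed(seed, 3))
  hit_rows <- list(); tracks <- list()
  typed <- gm_df[!is.na(gm_df$type_name), , drop = FALSE]
  typed <- typed[order(typed$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(typed))) {
    g <- typed[i, ]
    lay <- layoutDomains(strsplit(g$type_name, "")[[1]])
    if (!is.null(lay$hits)) {
      h <- lay$hits
      h$protein_id <- g$gene_id
      h$evalue <- 10^(-stats::runif(nrow(h), 15, 60))
      hit_rows[[length(hit_rows) + 1L]] <-
        h[, c("protein_id", "acc", "start", "end", "evalue")]
    }
    if (config$noise_frac > 0 && stats::runif(1) < config$noise_frac) {
      ns <- sample(50:200, 1)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = g$gene_id, acc = "PF00931", start = ns,
        end = ns + 99L, evalue = 10^(-stats::runif(1, 1, 6)))
    }
    track <- stats::runif(lay$protein_length, 0, 0.3)
    for (seg in lay$coils)
      track[seg[1]:seg[2]] <- stats::runif(seg[2] - seg[1] + 1L, 0.8, 0.99)
    tracks[[g$gene_id]] <- round(track, 4)
  }
  hits <- do.call(rbind, hit_rows)

  # --- stage 4: similarity hits (stream 4) -------------------------------
  set.seed(subSeed(seed, 4))
  sim_rows <- list()
  emit_pair <- function(a, b, bitscore) {
    al <- sample(200:600, 1)
    pid <- round(stats::runif(1, 60, 95), 1)
    ev <- 10^(-stats::runif(1, 30, 80))
    for (qq in list(c(a, b), c(b, a)))
      sim_rows[[length(sim_rows) + 1L]] <<- data.frame(
        query_id = qq[1], subject_id = qq[2], percent_identity = pid,
        alignment_length = al, evalue = ev, bitscore = bitscore,
        stringsAsFactors = FALSE)
  }
  for (j in seq_len(nrow(relations)))
    emit_pair(relations$gene_a[j], relations$gene_b[j],
              round(stats::runif(1, 300, 600)))
  # self hits and sub-best decoys exercise best-hit selection
  typed_ids <- sort(typed$gene_id)
  for (g in typed_ids[seq(1, length(typed_ids), by = 7)])
    sim_rows[[length(sim_rows) + 1L]] <- data.frame(
      query_id = g, subject_id = g, percent_identity = 100,
      alignment_length = 500L, evalue = 0, bitscore = 999,
      stringsAsFactors = FALSE)
  if (nrow(relations) >= 2) {
    decoy <- relations[relations$relation == "ortholog", , drop = FALSE]
    if (nrow(decoy) >= 2)
      emit_pair(decoy$gene_a[1], decoy$gene_b[2],
                100)  # lower bitscore than any planted best hit
  }
  sims <- do.call(rbind, sim_rows)

  # --- truth -------------------------------------------------------------
  arch_truth <- typed[, c("gene_id", "species", "type_name")]
  arch_truth$subclass <- ifelse(
    grepl("N", arch_truth$type_name) & grepl("L", arch_truth$type_name),
    "NBS-LRR", "non-NBS-LRR")
  arch_truth$is_nbs <- grepl("N", arch_truth$type_name)
  rownames(arch_truth) <- NULL
  members <- do.call(rbind, lin_members)
  members <- merge(members,
                   gm_out[, c("gene_id", "chromosome")], by = "gene_id",
                   sort = FALSE)[, c("lineage_id", "species", "gene_id",
                                     "chromosome", "type_name")]
  truth <- list(architectures = arch_truth,
                relations = relations,
                lineage_members = members,
                lineage_flags = do.call(rbind, lin_flags),
                seed = seed, config = config)

  # --- write files -------------------------------------------------------
  files <- c(gff = file.path(out_dir, "genes.gff3"),
             domain_hits = file.path(out_dir, "domain_hits.tsv"),
             coil_tracks = file.path(out_dir, "coil_tracks.tsv"),
             similarity = file.path(out_dir, "similarity.tsv"),
             collinearity = file.path(out_dir, "collinearity.txt"),
             species_tree = file.path(out_dir, "species.nwk"))
  writeGeneModels(gm_out, files[["gff"]])
  hit_df <- if (is.null(hits)) emptyDomainHits() else
    data.frame(protein_id = hits$protein_id, source = hits$acc,
               start = hits$start, end = hits$end, evalue = hits$evalue,
               stringsAsFactors = FALSE)
  writeDomainHits(hit_df, files[["domain_hits"]])
  writeCoilTracks(tracks, files[["coil_tracks"]])
  writeSimilarityHits(sims, files[["similarity"]])
  writeCollinearity(blocks, files[["collinearity"]])
  writeLines(paste0("(", paste(sp, collapse = ","), ");"),
             files[["species_tree"]])
  list(files = files, truth = truth,
       tables = list(gene_models = gm_out, blocks = blocks,
                     similarity = sims))
}

#' Configuration for the synthetic expression generator
#'
#' Defaults emulate a two-condition hormone-treatment design with three
#' independent replicates per condition: negative-binomial counts around
#' log-normal gene means, a planted set of up-regulated genes with a
#' multiplicative treatment effect, and optionally correlated gene blocks
#' (the first tied to the treatment) for module detection.
#'
#' @param n_genes total genes.
#' @param reps replicates per condition.
#' @param n_up planted up-regulated genes.
#' @param effect multiplicative treatment effect on up genes (1 = null).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param module_sizes integer vector of planted correlated block sizes;
#'   the first block's latent factor follows the treatment indicator.
#' @param mean_log,sd_log log-normal parameters of baseline gene means.
#' @param length_range transcript length range in bases.
#' @return a list of class \code{expr_config}.
#' @export
exprConfig <- function(n_genes = 500, reps = 3, n_up = 20, effect = 4,
                       dispersion = 0.005, module_sizes = c(40, 40),
                       mean_log = log(1000), sd_log = 0.5,
                       length_range = c(500, 5000)) {
  stopifnot(n_up + sum(module_sizes) <= n_genes, reps >= 2, effect > 0)
  structure(as.list(environment()), class = "expr_config")
}

#' Generate a synthetic two-condition expression fixture
#'
#' @param config an [exprConfig()] list.
#' @param seed master seed.
#' @param out_dir optional directory; when given, a count matrix (with a
#'   \code{length} column) and a design table are written there.
#' @return list with \code{counts}, \code{gene_lengths}, \code{design},
#'   \code{truth} (up genes, module memberships, seed) and \code{files}.
#' @export
generateExpression <- function(config = exprConfig(), seed = 1,
                               out_dir = NULL) {
  stopifnot(inherits(config, "expr_config"))
  set.seed(subSeed(seed, 11))
  G <- config$n_genes; R <- config$reps
  n_s <- 2L * R
  samples <- c(sprintf("trt_%d", seq_len(R)), sprintf("ctl_%d", seq_len(R)))
  condition <- rep(c("treated", "control"), each = R)
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  lens <- round(stats::runif(G, config$length_range[1],
                             config$length_range[2]))
  mu0 <- stats::rlnorm(G, config$mean_log, config$sd_log)
  # planted structure: up genes first, then module blocks
  up <- gene_ids[seq_len(config$n_up)]
  modules <- list()
  off <- config$n_up
  for (b in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[b]
    modules[[b]] <- gene_ids[off + seq_len(sz)]
    off <- off + sz
  }
  lmu <- matrix(log(mu0), G, n_s)
  lmu[seq_len(config$n_up), condition == "treated"] <-
    lmu[seq_len(config$n_up), condition == "treated"] + log(config$effect)
  trt <- as.numeric(condition == "treated")
  for (b in seq_along(modules)) {
    f <- if (b == 1) scale(trt)[, 1] + stats::rnorm(n_s, 0, 0.2) else
      stats::rnorm(n_s)
    gi <- match(modules[[b]], gene_ids)
    loading <- stats::runif(length(gi), 0.8, 1.2)
    lmu[gi, ] <- lmu[gi, ] + outer(loading, f)
  }
  counts <- matrix(stats::rnbinom(G * n_s, mu = exp(lmu),
                                  size = 1 / config$dispersion),
                   G, n_s, dimnames = list(gene_ids, samples))
  storage.mode(counts) <- "integer"
  design <- data.frame(sample = samples, condition = condition,
                       stringsAsFactors = FALSE)
  truth <- list(up_genes = up, modules = modules, seed = seed,
                config = config)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(counts = file.path(out_dir, "counts.tsv"),
               design = file.path(out_dir, "design.tsv"))
    cm <- data.frame(gene_id = gene_ids, length = lens, counts,
                     check.names = FALSE)
    utils::write.table(cm, files[["counts"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(design, files[["design"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(counts = counts,
       gene_lengths = stats::setNames(lens, gene_ids),
       design = design, truth = truth, files = files)
}

#' Generate a synthetic promoter cis-element table
#'
#' Plants element occurrences over a gene set with exact per-category
#' counts, drawing element names from the packaged category map; each
#' occurrence gets a position within the 2,000 bp upstream window. The
#' defaults reproduce the occurrence balance typical of an NBS-LRR
#' promoter survey: 161 hormone-related, 41 stress-responsive and 13
#' plant-growth occurrences over 22 genes.
#'
#' @param gene_ids genes to distribute elements over.
#' @param category_counts named integer vector of occurrences per category.
#' @param seed master seed.
#' @param out_dir optional directory to write the PlantCARE-style export.
#' @return list with \code{elements} (data.frame), \code{truth}
#'   (per-category counts and per-gene element lists) and \code{file}.
#' @export
generateCisElements <- function(gene_ids = sprintf("gene_%02d", 1:22),
                                category_counts = c(
                                  "hormone-related" = 161,
                                  "stress-responsive" = 41,
                                  "plant growth" = 13),
                                seed = 1, out_dir = NULL) {
  set.seed(subSeed(seed, 21))
  map <- loadCisCategoryMap()
  # the stress-responsive category is planted with fixed per-function
  # counts (defense/drought/low-temperature/wound); other categories draw
  # element names uniformly from their vocabulary
  stress_split <- c("TC-rich repeats" = 14, "MBS" = 15, "LTR" = 10,
                    "WUN-motif" = 2)
  rows <- list()
  for (k in names(category_counts)) {
    pool <- map[map$category == k, , drop = FALSE]
    n <- category_counts[[k]]
    if (k == "stress-responsive" && n == sum(stress_split)) {
      idx <- match(rep(names(stress_split), stress_split),
                   pool$element_name)
      pick <- pool[idx, ]
    } else {
      pick <- pool[sample.int(nrow(pool), n, replace = TRUE), ]
    }
    rows[[k]] <- data.frame(
      gene_id = sample(gene_ids, n, replace = TRUE),
      element_name = pick$element_name,
      position = sample.int(2000, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      function_label = pick$function_label, stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, rows)
  rownames(elements) <- NULL
  file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file <- file.path(out_dir, "cis_elements.tsv")
    utils::write.table(elements, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  truth <- list(category_counts = category_counts,
                genes_by_element = split(elements$gene_id,
                                         elements$element_name),
                seed = seed)
  list(elements = elements, truth = truth, file = file)
}
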