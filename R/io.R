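## File formats: phased VCF in; a versioned plain-text graph serialization
## ("GRG-lite") for save/load; GCTA-dialect .par / .phen and headered TSV
## tables out. All writers are deterministic: identical inputs give
## byte-identical files.

#' Read phased genotypes from a VCF file
#'
#' Requires phased diploid GT fields (`a|b`); an unphased separator (`/`) or
#' a missing allele (`.`) raises an error naming the offending record and
#' sample — the graph encodes hard calls only, and no imputation policy is
#' applied. Multiallelic records are split into one mutation per alternate
#' allele (allele code `k` becomes a 1 in the k-th split column). VCF
#' positions are kept 1-based, as in the file.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples Optional character vector restricting and ordering the
#'   samples to load.
#' @return A [genotype_matrix()] whose individual ids are the VCF sample
#'   names.
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF contains no samples", call. = FALSE)
  sample_names <- colnames(gt)[-1L]
  if (!is.null(samples)) {
    missing <- setdiff(samples, sample_names)
    if (length(missing)) {
      stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sample_names <- samples
  }
  n_rec <- nrow(gt)
  n_ind <- length(sample_names)

  if (is.null(n_rec) || n_rec == 0L) {
    return(genotype_matrix(matrix(0L, nrow = 2L * n_ind, ncol = 0L),
                           individual_ids = sample_names))
  }

  gt_fields <- sub(":.*$", "", gt[, sample_names, drop = FALSE])
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = 0L)
  cols <- vector("list", n_rec)
  meta <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    g <- gt_fields[r, ]
    if (anyNA(g)) {
      stop(sprintf("missing genotype at record %d (POS %s), sample %s",
                   r, fix$POS[r], sample_names[which(is.na(g))[1]]),
           call. = FALSE)
    }
    bad_sep <- grepl("/", g, fixed = TRUE)
    if (any(bad_sep)) {
      stop(sprintf("unphased genotype at record %d (POS %s), sample %s: '%s'",
                   r, fix$POS[r], sample_names[which(bad_sep)[1]],
                   g[which(bad_sep)[1]]), call. = FALSE)
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != 2L)) {
      stop(sprintf("record %d (POS %s), sample %s: expected a phased diploid GT, got '%s'",
                   r, fix$POS[r], sample_names[which(lens != 2L)[1]],
                   g[which(lens != 2L)[1]]), call. = FALSE)
    }
    alleles <- unlist(parts, use.names = FALSE)  # h1,h2 per sample in GT order
    if (any(alleles == ".")) {
      stop(sprintf("missing genotype at record %d (POS %s), sample %s",
                   r, fix$POS[r],
                   sample_names[ceiling(which(alleles == ".")[1] / 2)]),
           call. = FALSE)
    }
    codes <- as.integer(alleles)
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    cols[[r]] <- vapply(seq_along(alts),
                        function(k) as.integer(codes == k), integer(2L * n_ind))
    meta[[r]] <- data.frame(position = as.integer(fix$POS[r]),
                            ref = fix$REF[r], alt = alts,
                            stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  M <- ncol(values)
  muts <- data.frame(mutation_id = seq_len(M) - 1L,
                     position = meta$position, ref = meta$ref, alt = meta$alt,
                     frequency = NA_real_, stringsAsFactors = FALSE)
  genotype_matrix(values, mutations = muts, individual_ids = sample_names)
}

#' Write a genotype matrix as a minimal phased VCF
#'
#' One biallelic record per mutation with phased `a|b` GT fields; used to
#' round-trip the synthetic fixtures through [read_vcf()] and to feed the
#' command-line `construct` step.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param chrom Chromosome label for all records.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom = "1") {
  values <- gm$values
  n_ind <- nrow(values) %/% 2L
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$individual_ids), collapse = "\t"))
  lines <- character(ncol(values))
  for (i in seq_len(ncol(values))) {
    col <- values[, i]
    odd <- seq(1L, length(col), by = 2L)
    gts <- paste0(col[odd], "|", col[odd + 1L])
    lines[i] <- paste(c(chrom, format(gm$mutations$position[i], trim = TRUE,
                                      scientific = FALSE, digits = 15),
                        paste0("m", gm$mutations$mutation_id[i]),
                        gm$mutations$ref[i], gm$mutations$alt[i],
                        ".", "PASS", ".", "GT", gts), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

GRGLITE_VERSION <- 1L

#' Save / load a graph in the GRG-lite text format
#'
#' A versioned, line-oriented plain-text serialization so that graphs are
#' diffable and portable. Records (tab-separated):
#' \describe{
#'   \item{`grglite <version>`}{header, first line}
#'   \item{`H <2N>`}{haploid sample count}
#'   \item{`I <id>`}{one line per diploid individual, in order}
#'   \item{`M <id> <position> <ref> <alt> <frequency|.>`}{one per mutation}
#'   \item{`N <id> <mutations|.> <children|.>`}{one per node with mutations
#'     or children; comma-separated 0-based id lists}
#' }
#' `load_grg(save_grg(g))` reproduces an identical graph: same ids, edges
#' and mutation table.
#'
#' @param grg A `grg` object.
#' @param path File path.
#' @return `save_grg()`: `path` invisibly; `load_grg()`: a `grg`.
#' @export
save_grg <- function(grg, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste("grglite", GRGLITE_VERSION),
               paste("H", grg$n_haploid),
               paste("I", grg$individual_ids)), con)
  m <- grg$mutations
  freq <- ifelse(is.na(m$frequency), ".",
                 sprintf("%.17g", m$frequency))
  if (nrow(m)) {
    writeLines(paste("M", m$mutation_id,
                     format(m$position, trim = TRUE, scientific = FALSE,
                            digits = 15),
                     m$ref, m$alt, freq, sep = "\t"), con)
  }
  children <- grg_children(grg)
  mut_by_node <- split(grg$mutations$mutation_id, grg$mutation_node)
  node_ids <- sort(unique(c(as.integer(names(mut_by_node)),
                            which(lengths(children) > 0L) - 1L,
                            grg$n_nodes - 1L)))
  fmt_ids <- function(x) if (length(x)) paste(x, collapse = ",") else "."
  lines <- vapply(node_ids, function(n) {
    paste("N", n, fmt_ids(mut_by_node[[as.character(n)]]),
          fmt_ids(children[[n + 1L]]), sep = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname save_grg
#' @export
load_grg <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) {
    stop(sprintf("cannot load '%s': %s at line %d", path, why, i),
         call. = FALSE)
  }
  if (!length(lines)) bad(1L, "empty file")
  head_parts <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (head_parts[1] != "grglite") bad(1L, "not a GRG-lite file")
  if (as.integer(head_parts[2]) != GRGLITE_VERSION) {
    bad(1L, sprintf("unsupported format version %s (reader supports %d)",
                    head_parts[2], GRGLITE_VERSION))
  }
  n_haploid <- NA_integer_
  ind_ids <- character(0)
  mut_rows <- list()
  node_rows <- list()
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(line)) next
    tag <- substr(line, 1L, 1L)
    if (tag == "H") {
      n_haploid <- as.integer(strsplit(line, " ", fixed = TRUE)[[1]][2])
    } else if (tag == "I") {
      ind_ids <- c(ind_ids, strsplit(line, " ", fixed = TRUE)[[1]][2])
    } else if (tag == "M") {
      p <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(p) != 6L) bad(i, "malformed mutation record")
      mut_rows[[length(mut_rows) + 1L]] <- p
    } else if (tag == "N") {
      p <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(p) != 4L) bad(i, "malformed node record")
      node_rows[[length(node_rows) + 1L]] <- p
    } else {
      bad(i, sprintf("unknown record tag '%s'", tag))
    }
  }
  if (is.na(n_haploid)) bad(1L, "missing H record")

  parse_ids <- function(s) {
    if (s == ".") integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  M <- length(mut_rows)
  mutations <- if (M) {
    data.frame(
      mutation_id = vapply(mut_rows, function(p) as.integer(p[2]), integer(1)),
      position = vapply(mut_rows, function(p) as.numeric(p[3]), numeric(1)),
      ref = vapply(mut_rows, `[`, character(1), 4),
      alt = vapply(mut_rows, `[`, character(1), 5),
      frequency = vapply(mut_rows, function(p)
        if (p[6] == ".") NA_real_ else as.numeric(p[6]), numeric(1)),
      stringsAsFactors = FALSE)
  } else default_mutations(0L)
  mutations <- mutations[order(mutations$mutation_id), , drop = FALSE]

  mutation_node <- integer(M)
  max_node <- n_haploid - 1L
  kids <- list()
  for (p in node_rows) {
    n <- as.integer(p[2])
    max_node <- max(max_node, n)
    ch <- parse_ids(p[4])
    if (length(ch)) {
      kids[[as.character(n)]] <- ch
      max_node <- max(max_node, max(ch))
    }
    for (m in parse_ids(p[3])) mutation_node[m + 1L] <- n
  }
  children <- rep(list(integer(0)), max_node + 1L)
  for (nm in names(kids)) children[[as.integer(nm) + 1L]] <- kids[[nm]]

  grg(n_haploid, children, mutation_node, mutations = mutations,
      individual_ids = if (length(ind_ids)) ind_ids else NULL)
}

#' Write causal effects as a GCTA-style .par file
#'
#' Whitespace-delimited, headerless, with columns in the order
#' `mutation_id`, `AlternateAllele`, `Position`, `RefAllele`, `Frequency`,
#' `Effect` — one file per trait, one line per causal mutation.
#'
#' @param effects An effect table (see [draw_effects()]) with columns
#'   `mutation_id`, `trait_id`, `effect_size`.
#' @param mutations Mutation metadata table (as in a `grg`).
#' @param frequencies Numeric vector of alternate-allele frequencies, one
#'   per mutation in the metadata table.
#' @param path Output path. With several traits, the 0-based trait index is
#'   inserted before the extension (e.g. `out.par` -> `out.trait1.par`).
#' @return Character vector of the paths written, invisibly.
#' @export
write_par <- function(effects, mutations, frequencies, path) {
  effects <- validate_effect_table(effects, mutations$mutation_id)
  traits <- sort(unique(effects$trait_id))
  multi <- length(traits) > 1L
  paths <- character(0)
  for (tr in traits) {
    sub <- effects[effects$trait_id == tr, , drop = FALSE]
    sub <- sub[order(sub$mutation_id), , drop = FALSE]
    idx <- match(sub$mutation_id, mutations$mutation_id)
    out_path <- if (multi) trait_path(path, tr) else path
    lines <- sprintf("%d\t%s\t%s\t%s\t%s\t%s",
                     sub$mutation_id, mutations$alt[idx],
                     format(mutations$position[idx], trim = TRUE,
                            scientific = FALSE),
                     mutations$ref[idx],
                     sprintf("%.17g", frequencies[idx]),
                     sprintf("%.17g", sub$effect_size))
    writeLines(lines, out_path)
    paths <- c(paths, out_path)
  }
  if (!length(traits)) {  # no causal mutations: an empty file
    writeLines(character(0), path)
    paths <- path
  }
  invisible(paths)
}

trait_path <- function(path, trait) {
  sub("(\\.[^.]+)$", sprintf(".trait%d\\1", trait), path)
}

#' Read a .par file back into an effect table
#'
#' @param path A file written by [write_par()] (or GCTA).
#' @param trait_id Trait index to assign to the rows.
#' @return Data frame with columns `mutation_id`, `trait_id`, `effect_size`,
#'   plus the allele/position/frequency columns from the file.
#' @export
read_par <- function(path, trait_id = 0L) {
  if (file.size(path) == 0L) {
    return(data.frame(mutation_id = integer(0), trait_id = integer(0),
                      effect_size = numeric(0)))
  }
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("mutation_id", "alt", "position", "ref", "frequency",
                  "effect_size")
  data.frame(mutation_id = as.integer(tab$mutation_id),
             trait_id = as.integer(trait_id),
             effect_size = as.numeric(tab$effect_size),
             alt = tab$alt, position = tab$position, ref = tab$ref,
             frequency = tab$frequency, stringsAsFactors = FALSE)
}

#' Write phenotypes as a GCTA-style .phen file
#'
#' Default dialect is headerless two-column (`person_id`, `phenotype`), one
#' line per individual in individual order. `id_style = "fid_iid"`
#' duplicates the id into family/individual columns (the GCTA convention);
#' `header = TRUE` prepends column names. With several traits one file per
#' trait is written (trait index inserted before the extension).
#'
#' @param pheno A phenotype table (see [sim_phenotypes()]).
#' @param path Output path.
#' @param header Prepend a header line.
#' @param id_style `"single"` or `"fid_iid"`.
#' @return Character vector of paths written, invisibly.
#' @export
write_phen <- function(pheno, path, header = FALSE,
                       id_style = c("single", "fid_iid")) {
  id_style <- match.arg(id_style)
  df <- as.data.frame(pheno)
  if (nrow(df) && any(!is.finite(df$phenotype))) {
    stop("non-finite phenotype value; refusing to write .phen", call. = FALSE)
  }
  traits <- sort(unique(df$trait_id))
  if (!length(traits)) traits <- 0L
  multi <- length(traits) > 1L
  paths <- character(0)
  for (tr in traits) {
    sub <- df[df$trait_id == tr, , drop = FALSE]
    out_path <- if (multi) trait_path(path, tr) else path
    val <- sprintf("%.17g", sub$phenotype)
    body <- if (id_style == "fid_iid") {
      paste(sub$individual_id, sub$individual_id, val, sep = "\t")
    } else {
      paste(sub$individual_id, val, sep = "\t")
    }
    head_line <- if (id_style == "fid_iid") "FID\tIID\tphenotype"
                 else "person_id\tphenotype"
    writeLines(c(if (header) head_line, body), out_path)
    paths <- c(paths, out_path)
  }
  invisible(paths)
}

#' Write an intermediate pipeline table as headered TSV
#'
#' Internal trait indices are emitted under the column name
#' `causal_mutation_id`, the trait-grouping column of the pipeline's output
#' schema.
#'
#' @param df A pipeline data frame (effects, genetic values, phenotypes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  names(df)[names(df) == "trait_id"] <- "causal_mutation_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
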