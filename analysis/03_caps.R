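#!/usr/bin/env Rscript
# fMRI CAP stage: z-score each subject's ROI run, pool all frames, cluster
# them with cosine k-means (k = 14), name each CAP from its Wilcoxon z-map
# via the 7-network atlas, and write per-subject temporal metrics.

suppressMessages(library(neurostate))

seed <- 3L
data_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

atlas <- read_atlas(file.path(data_dir, "atlas.tsv"))
files <- list.files(file.path(data_dir, "bold"), pattern = "\\.tsv$",
                    full.names = TRUE)
stopifnot(length(files) > 0)
ids <- sub("\\.tsv$", "", basename(files))

message("Z-scoring and pooling ", length(files), " ROI runs ...")
runs <- lapply(files, function(f)
  zscore_roi(read_roi_table(f, tr = 2, atlas = atlas)))
frames <- do.call(rbind, lapply(runs, function(r) r$data))

message("Clustering ", nrow(frames), " frames into 14 CAPs ...")
caps <- cap_cluster(frames, k = 14, n_restarts = 50, seed = seed)

labels_all <- assign_frames(frames, caps)
zm <- cap_zscores(frames, labels_all, atlas)
caps$names <- zm$names
utils::write.table(cbind(name = zm$names, as.data.frame(caps$centroids)),
                   "results/cap_centroids.tsv", sep = "\t", row.names = FALSE)
write_report(list(names = zm$names,
                  network_z = apply(zm$network_z, 1, function(r)
                    as.list(stats::setNames(r, colnames(zm$network_z))))),
             "results/cap_names.json")

rows <- list()
for (i in seq_along(runs)) {
  lab <- assign_frames(runs[[i]], caps)
  cm <- cap_temporal_metrics(lab, tr = runs[[i]]$tr, k = caps$k)
  meta <- strsplit(ids[i], "_")[[1]]
  rows[[i]] <- cbind(subject_id = meta[1], timepoint = meta[2],
                     cap = zm$names[cm$state], cm)
}
write_metrics_tsv(do.call(rbind, rows), "results/cap_metrics.tsv")

message("CAP names: ", paste(sort(unique(zm$names)), collapse = ", "))
message("Wrote results/cap_metrics.tsv (", length(rows) * caps$k, " rows).")
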