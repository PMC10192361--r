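# Example promdiv pipeline configuration (fully synthetic inputs).
# Each data kind takes either a `simulate` block or input paths, never both.
version: 1
seed: 1
output_dir: promdiv_out

alignments:
  control: control          # group providing Se^C and the chi-squared null
  simulate:
    n_species: 5
    seq_length: 2000
    sub_prob: 0.02          # per-site substitution probability per species
    indel_len_p: 0.5        # geometric length parameter, minimum length 1
    tss_position: 1000      # reference coordinate anchored as offset 0
    groups:
      - {name: control, n_genes: 6, indel_rate: 1}   # events per kb
      - {name: IR,      n_genes: 6, indel_rate: 3}
      - {name: OR,      n_genes: 6, indel_rate: 3}
  # paths: {dir: alignments/, annotations: annotations.tsv, reference: dmel}

mkt:
  compare: [nup, genome]
  simulate:
    mean_ps: 20
    mean_ds: 20
    pn_ps_ratio: 0.3
    groups:
      - {name: nup,    n_genes: 200, true_alpha: 0.4}
      - {name: genome, n_genes: 200, true_alpha: 0.0}
  # path: mkt_counts.tsv    # gene_id, Pn, Ps, Dn, Ds, group

conservation:
  control: genome
  simulate:
    base_mean: 1.0
    noise_sd: 0.1
    drop_window: [-380, -30]
    groups:
      - {name: nup,    n_genes: 50, promoter_drop: 0.5}
      - {name: genome, n_genes: 50, promoter_drop: 0.0}
  # paths: {scores: phylop.bedgraph, annotations: tss.tsv}

params:
  half_window: 5            # Se window: 5 nt up- and downstream
  promoter_window: [-380, -30]
  anchor_window: [-1000, 1000]
  mc_reps: 100000           # G-test Monte Carlo replicates
  bootstrap_k: 30
  bootstrap_b: 100
  comparison: reference     # or any_pair
  alpha: 0.05
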