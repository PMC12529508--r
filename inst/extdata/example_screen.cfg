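# Example pipeline configuration (flat key: value with dotted sections).

# synthetic screen (cyscreen simulate)
sim.seed: 7
sim.n_proteins: 20
sim.conditions: KB2, KB7, SO56
sim.replicates: 2
sim.sigma_bg: 0.25
sim.sigma_rep: 0.30
sim.missingness: 0.10
sim.plant_fraction: 0.10
sim.plant_effect: 3

# analysis (cyscreen run)
paths.proteome: screen/proteome.fasta
paths.psms: screen/psms.tsv
paths.outdir: results
scheme: biotin-azide
call.threshold: 2
call.sd_gate: 2
call.anti_threshold: -2
call.excluded_compounds: SO56, SO59
call.required_replicates: 2
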