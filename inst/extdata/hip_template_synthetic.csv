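# Reconstructed hierarchical gating template for the synthetic immunophenotyping
# panel of defaultPanelSpec(): scatter/viability pre-gates, the major lineage
# populations and the three-marker k-means T-cell subset row. The original
# study template is not public; this is a synthetic reconstruction of the
# Human Immunology Project-style hierarchy for use with generated data.
alias,parent,dims,method,sign,args
singlets,root,FSC-A:FSC-H,singlet,,band_k=4
live,singlets,LiveDead,mindensity,-,"min_peak_height=0.02;gate_range=[-1,5]"
lymphocytes,live,FSC-A:SSC-A,rect,,"bounds=[55000,95000,5000,55000]"
Tcells,lymphocytes,CD3:CD19,quadrant,+-,
Bcells,lymphocytes,CD3:CD19,quadrant,-+,
NK,lymphocytes,CD16:CD56,quadrant,++,
monocytes,live,CD20:CD14,quadrant,-+,
linNeg,live,,boolean,,expr=live&!Tcells&!Bcells&!NK&!monocytes
dendritic,linNeg,HLA-DR,mindensity,+,
CD4,Tcells,CD4:CD8,quadrant,+-,
CD8,Tcells,CD4:CD8,quadrant,-+,
Tsubsets,Tcells,CCR7:CD45RA:CD28,kmeans_subsets,,markers=CCR7:CD45RA:CD28;parents=CD4:CD8;seed=42
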