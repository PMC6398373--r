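drug	target	fda_approved	n_trials
tipifarnib	RHOB	TRUE	3
calcitriol	VDR	TRUE	12
celecoxib	PTGS2	TRUE	2
rofecoxib	PTGS2	TRUE	2
valdecoxib	PTGS2	TRUE	2
etoricoxib	PTGS2	TRUE	2
parecoxib	PTGS2	TRUE	2
lumiracoxib	PTGS2	TRUE	2
diclofenac	PTGS2	TRUE	2
ibuprofen	PTGS2	TRUE	2
naproxen	PTGS2	TRUE	2
indomethacin	PTGS2	TRUE	2
ketoprofen	PTGS2	TRUE	2
ketorolac	PTGS2	TRUE	2
meloxicam	PTGS2	TRUE	2
piroxicam	PTGS2	TRUE	2
sulindac	PTGS2	TRUE	2
etodolac	PTGS2	TRUE	2
nabumetone	PTGS2	TRUE	2
oxaprozin	PTGS2	TRUE	2
flurbiprofen	PTGS2	TRUE	2
tolmetin	PTGS2	TRUE	2
quercetin	PIM1	FALSE	7
apricoxib	PTGS2	FALSE	5
hmox1-ligand-01	HMOX1	FALSE	0
hmox1-ligand-02	HMOX1	FALSE	0
hmox1-ligand-03	HMOX1	FALSE	0
hmox1-ligand-04	HMOX1	FALSE	0
hmox1-ligand-05	HMOX1	FALSE	0
hmox1-ligand-06	HMOX1	FALSE	0
hmox1-ligand-07	HMOX1	FALSE	0
hmox1-ligand-08	HMOX1	FALSE	0
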