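name	hemisphere	subtype	grouping
DN-L-dmPFC-1	L	dmPFC	PFC
DN-L-dmPFC-2	L	dmPFC	PFC
DN-L-dmPFC-3	L	dmPFC	PFC
DN-L-dmPFC-4	L	dmPFC	PFC
DN-R-dmPFC-1	R	dmPFC	PFC
DN-R-dmPFC-2	R	dmPFC	PFC
DN-R-dmPFC-3	R	dmPFC	PFC
DN-R-dmPFC-4	R	dmPFC	PFC
DN-L-vmPFC-1	L	vmPFC	PFC
DN-L-vmPFC-2	L	vmPFC	PFC
DN-L-vmPFC-3	L	vmPFC	PFC
DN-L-vmPFC-4	L	vmPFC	PFC
DN-R-vmPFC-1	R	vmPFC	PFC
DN-R-vmPFC-2	R	vmPFC	PFC
DN-R-vmPFC-3	R	vmPFC	PFC
DN-R-vmPFC-4	R	vmPFC	PFC
DN-L-OFC-1	L	OFC	PFC
DN-L-OFC-2	L	OFC	PFC
DN-L-OFC-3	L	OFC	PFC
DN-R-OFC-1	R	OFC	PFC
DN-R-OFC-2	R	OFC	PFC
DN-R-OFC-3	R	OFC	PFC
DN-L-vlPFC-1	L	vlPFC	PFC
DN-L-vlPFC-2	L	vlPFC	PFC
DN-L-vlPFC-3	L	vlPFC	PFC
DN-R-vlPFC-1	R	vlPFC	PFC
DN-R-vlPFC-2	R	vlPFC	PFC
DN-R-vlPFC-3	R	vlPFC	PFC
DN-L-dlPFC-1	L	dlPFC	PFC
DN-L-dlPFC-2	L	dlPFC	PFC
DN-L-dlPFC-3	L	dlPFC	PFC
DN-R-dlPFC-1	R	dlPFC	PFC
DN-R-dlPFC-2	R	dlPFC	PFC
DN-R-dlPFC-3	R	dlPFC	PFC
DN-L-PCC-1	L	PCC	PCC-RSC
DN-L-PCC-2	L	PCC	PCC-RSC
DN-L-PCC-3	L	PCC	PCC-RSC
DN-L-PCC-4	L	PCC	PCC-RSC
DN-L-PCC-5	L	PCC	PCC-RSC
DN-L-PCC-6	L	PCC	PCC-RSC
DN-R-PCC-1	R	PCC	PCC-RSC
DN-R-PCC-2	R	PCC	PCC-RSC
DN-R-PCC-3	R	PCC	PCC-RSC
DN-R-PCC-4	R	PCC	PCC-RSC
DN-R-PCC-5	R	PCC	PCC-RSC
DN-L-RSC-1	L	RSC	PCC-RSC
DN-L-RSC-2	L	RSC	PCC-RSC
DN-L-RSC-3	L	RSC	PCC-RSC
DN-L-RSC-4	L	RSC	PCC-RSC
DN-R-RSC-1	R	RSC	PCC-RSC
DN-R-RSC-2	R	RSC	PCC-RSC
DN-R-RSC-3	R	RSC	PCC-RSC
DN-R-RSC-4	R	RSC	PCC-RSC
DN-L-pCun-1	L	pCun	PCC-RSC
DN-L-pCun-2	L	pCun	PCC-RSC
DN-L-pCun-3	L	pCun	PCC-RSC
DN-R-pCun-1	R	pCun	PCC-RSC
DN-R-pCun-2	R	pCun	PCC-RSC
DN-R-pCun-3	R	pCun	PCC-RSC
DN-L-Temp-1	L	Temp	temporal
DN-L-Temp-2	L	Temp	temporal
DN-L-Temp-3	L	Temp	temporal
DN-L-Temp-4	L	Temp	temporal
DN-L-Temp-5	L	Temp	temporal
DN-R-Temp-1	R	Temp	temporal
DN-R-Temp-2	R	Temp	temporal
DN-R-Temp-3	R	Temp	temporal
DN-R-Temp-4	R	Temp	temporal
DN-R-Temp-5	R	Temp	temporal
DN-L-STS-1	L	STS	temporal
DN-L-STS-2	L	STS	temporal
DN-L-STS-3	L	STS	temporal
DN-L-STS-4	L	STS	temporal
DN-R-STS-1	R	STS	temporal
DN-R-STS-2	R	STS	temporal
DN-R-STS-3	R	STS	temporal
DN-R-STS-4	R	STS	temporal
DN-L-TempPole-1	L	TempPole	temporal
DN-R-TempPole-1	R	TempPole	temporal
DN-L-TPJ-1	L	TPJ	parietal
DN-L-TPJ-2	L	TPJ	parietal
DN-L-TPJ-3	L	TPJ	parietal
DN-R-TPJ-1	R	TPJ	parietal
DN-R-TPJ-2	R	TPJ	parietal
DN-R-TPJ-3	R	TPJ	parietal
DN-L-IPL-1	L	IPL	parietal
DN-L-IPL-2	L	IPL	parietal
DN-L-IPL-3	L	IPL	parietal
DN-R-IPL-1	R	IPL	parietal
DN-R-IPL-2	R	IPL	parietal
DN-R-IPL-3	R	IPL	parietal
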