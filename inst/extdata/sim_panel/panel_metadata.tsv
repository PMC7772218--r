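accession_id	subgroup	origin
WLD_001	WLD	deme1
WLD_002	WLD	deme2
WLD_003	WLD	deme3
WLD_004	WLD	deme4
WLD_005	WLD	deme1
WLD_006	WLD	deme2
WLD_007	WLD	deme3
WLD_008	WLD	deme4
WLD_009	WLD	deme1
WLD_010	WLD	deme2
WLD_011	WLD	deme3
WLD_012	WLD	deme4
NS_001	NS	native_selection
NS_002	NS	native_selection
NS_003	NS	native_selection
NS_004	NS	native_selection
NS_005	NS	native_selection
NS_006	NS	native_selection
NS_007	NS	native_selection
NS_008	NS	native_selection
NS_009	NS	native_selection
NS_010	NS	native_selection
NS_011	NS	native_selection
NS_012	NS	native_selection
CLT1_001	CLT1	founder_cross
CLT1_002	CLT1	founder_cross
CLT1_003	CLT1	founder_cross
CLT1_004	CLT1	founder_cross
CLT1_005	CLT1	founder_cross
CLT1_006	CLT1	founder_cross
CLT1_007	CLT1	founder_cross
CLT1_008	CLT1	founder_cross
CLT2_001	CLT2	advanced_cross
CLT2_002	CLT2	advanced_cross
CLT2_003	CLT2	advanced_cross
CLT2_004	CLT2	advanced_cross
CLT2_005	CLT2	advanced_cross
CLT2_006	CLT2	advanced_cross
CLT2_007	CLT2	advanced_cross
CLT2_008	CLT2	advanced_cross
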