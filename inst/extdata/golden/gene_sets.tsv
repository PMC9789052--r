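label	gene_id
RiboSET	GENE0016
RiboSET	GENE0027
RiboSET	GENE0029
RiboSET	GENE0039
RiboSET_ext	GENE0016
RiboSET_ext	GENE0027
RiboSET_ext	GENE0029
RiboSET_ext	GENE0039
PhyloSET	GENE0016
PhyloSET	GENE0027
PhyloSET	GENE0029
PhyloSET	GENE0039
UntranslSET	GENE0001
UntranslSET	GENE0002
UntranslSET	GENE0003
UntranslSET	GENE0004
UntranslSET	GENE0005
UntranslSET	GENE0007
UntranslSET	GENE0008
UntranslSET	GENE0009
UntranslSET	GENE0010
UntranslSET	GENE0011
UntranslSET	GENE0012
UntranslSET	GENE0013
UntranslSET	GENE0015
UntranslSET	GENE0017
UntranslSET	GENE0018
UntranslSET	GENE0019
UntranslSET	GENE0021
UntranslSET	GENE0025
UntranslSET	GENE0028
UntranslSET	GENE0030
UntranslSET	GENE0031
UntranslSET	GENE0032
UntranslSET	GENE0033
UntranslSET	GENE0034
UntranslSET	GENE0036
UntranslSET	GENE0037
UntranslSET	GENE0038
UntranslSET	GENE0040
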