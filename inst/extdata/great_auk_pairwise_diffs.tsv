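sample	MK131_LastGA1	MK133_Oldenburg	MK134_Bremen	MK135_Brussels	MK136_LA	MK138_Kiel	LastGA2_Heart
MK131_LastGA1							
MK133_Oldenburg	17						
MK134_Bremen	18	23					
MK135_Brussels	0	17	18				
MK136_LA	16	23	20	16			
MK138_Kiel	14	11	20	14	20		
LastGA2_Heart	16	23	20	16	18	20	
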