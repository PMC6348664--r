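subset,gene,delta_ct,bestkeeper,normfinder,genorm
All samples,RPL4,1,5,2,1
All samples,RPL18,2,3,4,1
All samples,HIS3,3,1,3,4
All samples,TUA3,4,2,1,6
All samples,SAMDC,11,11,11,11
All samples,TIP41,6,4,7,3
All samples,UGPase,8,6,8,7
All samples,18S,9,9,9,9
All samples,GAPDH,7,8,6,8
All samples,PIP2,10,10,10,10
All samples,ACT,5,7,5,5
Fruits,RPL4,5,6,4,7
Fruits,RPL18,1,3,1,4
Fruits,HIS3,6,8,7,3
Fruits,TUA3,7,5,5,8
Fruits,SAMDC,11,11,11,11
Fruits,TIP41,4,9,6,1
Fruits,UGPase,9,2,9,9
Fruits,18S,3,7,3,5
Fruits,GAPDH,2,1,2,6
Fruits,PIP2,10,4,10,10
Fruits,ACT,8,10,8,1
Floral tissues,RPL4,5,10,5,5
Floral tissues,RPL18,2,2,2,1
Floral tissues,HIS3,3,1,3,1
Floral tissues,TUA3,8,9,7,9
Floral tissues,SAMDC,11,11,11,11
Floral tissues,TIP41,7,6,8,4
Floral tissues,UGPase,1,1,1,3
Floral tissues,18S,9,3,9,7
Floral tissues,GAPDH,6,8,6,6
Floral tissues,PIP2,10,7,10,10
Floral tissues,ACT,4,5,4,8
Ovules and seeds,RPL4,8,7,8,5
Ovules and seeds,RPL18,7,3,7,3
Ovules and seeds,HIS3,9,9,9,9
Ovules and seeds,TUA3,2,4,2,4
Ovules and seeds,SAMDC,5,1,6,1
Ovules and seeds,TIP41,1,2,1,1
Ovules and seeds,UGPase,10,10,10,10
Ovules and seeds,18S,4,6,5,8
Ovules and seeds,GAPDH,6,8,4,7
Ovules and seeds,PIP2,11,11,11,11
Ovules and seeds,ACT,3,5,3,6
Vegetative tissues,RPL4,2,4,2,3
Vegetative tissues,RPL18,1,1,1,4
Vegetative tissues,HIS3,7,5,7,6
Vegetative tissues,TUA3,4,2,3,5
Vegetative tissues,SAMDC,11,9,11,11
Vegetative tissues,TIP41,3,6,4,1
Vegetative tissues,UGPase,5,8,5,7
Vegetative tissues,18S,9,11,9,10
Vegetative tissues,GAPDH,10,7,10,9
Vegetative tissues,PIP2,8,3,8,8
Vegetative tissues,ACT,6,10,6,1
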