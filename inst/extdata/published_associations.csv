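species,life_form,association
Betula platyphylla,tree,B(+) D(-)
Fraxinus chinensis,tree,D(+)
Symplocos paniculata,shrub,B(+) D(-)
Ailanthus altissima,tree,D(+)
Cornus controversa,tree,NA
Quercus serrata var. brevipetiolata,tree,NA
Carpinus turczaninowii,tree,C(+) D(-)
Acer davidii subsp. grosseri,tree,NA
Alangium platanifolium,shrub,D(+)
Malus honanensis,shrub,C(-) D(+)
Malus hupehensis,tree,NA
Sorbus hupehensis,shrub,D(+)
Lonicera tatarinowii,shrub,NA
Tilia japonica,tree,NA
Pinus armandii,tree,C(+)
Corylus chinensis,tree,NA
Crataegus wilsonii,shrub,NA
Viburnum betulifolium,shrub,B(+)
Cotoneaster acutifolius,shrub,D(+)
Viburnum opulus var. sargentii,shrub,NA
Betula chinensis,tree,NA
Sambucus williamsii,shrub,D(+)
Cornus macrophylla,tree,NA
Forsythia suspensa,shrub,C(+)
Betula luminifera,tree,NA
Euptelea pleiosperma,tree,NA
Abelia biflora,shrub,D(+)
Larix gmelinii,tree,NA
Cornus walteri,tree,A(+)
Celastrus orbiculatus,shrub,NA
Meliosma veitchiorum,tree,D(-)
Toxicodendron vernicifluum,tree,A(+) D(-)
Carpinus cordata,tree,D(-)
Litsea tsinlingensis,tree,D(+)
Berberis circumserrata,shrub,D(+)
Acer davidii,tree,NA
Quercus aliena var. acutiserrata,tree,C(-)
Lindera obtusiloba,tree,NA
Philadelphus incanus,shrub,D(+)
Populus davidiana,tree,D(+)
Cerasus serrulata,tree,NA
Tilia paucicostata,tree,C(+)
Salix shihtsuanensis,shrub,NA
Euonymus phellomanus,shrub,D(+)
Quercus variabilis,tree,NA
Sorbus alnifolia,tree,NA
Cornus kousa subsp. chinensis,shrub,B(+) D(-)
Cerasus clarofolia,shrub,B(-)
Acer pictum subsp. mono,tree,B(-) D(+)
Salix chaenomeloides,tree,D(+)
Juglans cathayensis,tree,NA
Pinus tabuliformis,tree,B(-)
Yulania denudata,tree,NA
Styrax obassis,tree,NA
Acer truncatum,tree,NA
Rhododendron micranthum,shrub,NA
Corylus heterophylla,tree,B(+)
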